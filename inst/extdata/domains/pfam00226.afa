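>pfam00226_seed1
QYKPDGDNSLGTIPHHTSGGDEYMDWNCSCAWMLYRWDAMTEYSVKRKCPIMPPAVIHHDHMNMMNQGSKEGMTSTYNYC
>pfam00226_seed2
QYKPDGINSLHTLPHHQSGGDEYMDWCCSCVKMLERWNAMTEVSDHRKCPSMGDAVIHHDHMNMMNQGSKEGMTSAYVYC
>pfam00226_seed3
QYKPDGDNSLTTLPHHTSGGDEYEDWCCSCAKMLERWNAATEVMDKRKTPIMKPAVIHCDHMNMMNQGSKHGMTSAYVNC
>pfam00226_seed4
QYKPDGDNPLCTLMHHTSGEDEYMDWCCSCAKMLERWNAMTEESDKRKCPIMPPGVIHHDHHNMMNQGSKEGHTSAYVYF
>pfam00226_seed5
QYKPDGDNSKCTLPHHTSGGDEFMDWCCSCAKMLERVNAMMEVSDKRKCPIMPPAVIHHDHMNMKNQGSKEGMTSAYVYC
>pfam00226_seed6
QYKPDGDNSLQTLPHHTSGGDEYMDWCCSCRKMLERWNAMTEVSDKRKCPIGAPAVIHLDHFNMMNQGSKENRTSAYVYC
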