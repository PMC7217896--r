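>pfam00011_seed1
NNLRQDTSEERYNYCRGEKSQQDNKNQEKEAASHDDDDCTGLNWQCFIGCRYHECMAEKQYFQHQPFHCVRDEFCPVCYR
>pfam00011_seed2
NNLRQDTSKEEYLYCRGEKSNQDNTNQETEAVSWDDDDCTGLPWQHFIGCRYHNCMAEKQYFQHQIFHCVRDEFVPVCYR
>pfam00011_seed3
NNDRQDTSEEEYLYCRGEKSHQDNKNQETEAASYDDDDCTGLPWQCRIGCRYHNYMAEKQYFQHQPCHCVQTEFCPVCYR
>pfam00011_seed4
NNLRQRSSEEEYLYCRGEDQQQDNKNQETEAASHDDDDCTGKPWQCFRGCRFHMCMIQREYFKHEPFHCVQDEFCLECYR
>pfam00011_seed5
NNRRQDTSEEEYLYCRGEKSQQDCKRQETGAASHDDDDCTGLPWQIFIGCRYHNEQAEKQYFQIQFFHCVRKEFCRVCYR
>pfam00011_seed6
NNLRQDTSEEAYDYCRGEKSQQGNKNQETEAASHDDDFCTGLPWQCFIGCRYHNCMAEKQYFQHQPFHCVRDEFCPVCYR
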