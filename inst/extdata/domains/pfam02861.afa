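>pfam02861_seed1
RNTHSIMWPEEKEGIPKDSGRMAGNHGFHRWYDTEIWLDCNCHWQRGHNSGRTPMGRWFKARRQKSKAIINIGYSEGWRF
>pfam02861_seed2
RNPHSIMWKEEKEGQPKDSGRMAGNAGFHWNYDTEEWLDCNCHWKKGHNSGRTPMGRWFKARCQKSKAIINPGTSEGWNF
>pfam02861_seed3
RSVHSIMWKEEKEGQPKDYMRMAGNAGFHWNYATQIWRDCNCHWAKGHNSGRTPQGRWFKARRQKSKAIINPGTSEGWNF
>pfam02861_seed4
RNPHSIMWKEEKEGMPKDSGRMAGNGGFHWNYDTEKWLDPNCHWAKGHNSGRTPMGRTFKARRQSSKAIINPGTSEGWNF
>pfam02861_seed5
RNPGSIIWKEEKEGQPKDSQRMAGNWGFHWNYHCEIWLDCNCHWAKGHNSGRTPMGRWFKACRQKSWAIIRPGTSQGWNF
>pfam02861_seed6
RNPHSIMWKEEKEGQPKDSGRMAGHAGFHWNYDTEIWLDCNCHWAKGHNSGRTPMGRWFKQRRQKSKDIINPGTSEGWNF
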