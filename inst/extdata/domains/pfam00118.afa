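>pfam00118_seed1
HLRWCCCVGNQGYDMQTWWLTYASLPCEHIKYNCGWQSYIPLFSMNSRRHIIYQTSLLLSYIRMETSYFAGYNLKQKLFK
>pfam00118_seed2
HLRWCCCVGDPGYDMQTWALTTASLPFEHIKYNCGHYNSFPLFSQNSRCHIIYQTSLLLYYIRMETSYCALYNLKQKLFS
>pfam00118_seed3
HLRWICCDGSPGYDMGTWLLTYASTPFEVIKWNCGWYAYIPLFSMNSRCHIIYQTSGLLSYIRMETSYCALYNPKYKLFR
>pfam00118_seed4
HLLWCCCVADPGYDDSTWYLTYASLPWEHIKQNCIWYNYIWLFFMNSRCDIIYQTSLLLSYIRMETSYCALYNLNQKLFK
>pfam00118_seed5
HGRWCCCVGDPGYDMQTWLLPYASLPFDHIKYECGWHNYIPLFLMWSRCHIIYQTSLLYSYIRYETSCCALYNLKQKLFS
>pfam00118_seed6
HLPWCCCVGDPGYDMQTWLLWYASLPFEHIVYDKGWYNYIPLFSMNSRMHIIYQTSLLLSYIRMEHSYCQLYNLKQKLFS
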