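>pfam02518_seed1
MYTYSLMHWFSQDIAHGDIHYRFQFMCATSKIHVINYMKYLGHSMMKRLGKFHILFWQMHEHSVTSGLNDWNTGELKNSC
>pfam02518_seed2
QYTYWLMREFSQDIAHQDQHYWFQFMCATSTIHVINYETYLGHSMMKRLGQLHILFWQMHEHIVKGGLNDWNDGEDKNSC
>pfam02518_seed3
QYTHWLMHEFSQLIAHQDQHYRFQFMSATSKIHVINYWKYLGHSMMKRLGQLHILFWQMHEHIVTEGLNDWNYGELKNSC
>pfam02518_seed4
QYVYWLMHEFSQDIAHRDQHYRFSFMCATSKIHVINYDKNLGHSMMKRLGSLHILFWQMHEHIVTGGGNDWNDIELKNSC
>pfam02518_seed5
QGTYWLMAEFDQDIAHGDQHYRFQFMCATSKIHVINYEKYLGHSMMKRLGQLHILFWHMHEHIVTGGLNDENDGELMNDC
>pfam02518_seed6
QYTYWLMHEFSQDIAHQDQHYRFQFMEATSKIGVINYEKYLGFSMMKRLGQLHITFWQMPEHISTGGLNDWNDGELKNSC
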