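>pfam07724_seed1
NGSRFWLLVRWQNDACAHFKSIPAIIEPMCCISPGNEFMQGSYFSKYMGSISKDFAQIEKCQNRYRMCPSLAGCIKDKPM
>pfam07724_seed2
NGSRFWLLVRWQNDACASCKSIPAKIEPMCCIVPGNEFMNGSYFSKYMGGIRKDFMQIEKCINMYRMCPYLAGCIKDKPM
>pfam07724_seed3
NGSRFWLLVRWQNDACAHCKSIPAKIAPMCCISPGNEFMQGSYFSKYMGGIRKDFMQQEKCINMYRMCPYWAICIKDKPM
>pfam07724_seed4
EGSRFWLLVRWQNDACAHCKSIPAKIEPMCCISPGNEFMQGSYFSKYMGGIRKDFMQIEKCINMYRMCPKRAYCIKDKPM
>pfam07724_seed5
NGSRFWLLVRWQNDACAHCKSIPAKIEPMCCINPGNEFMKGSYFSKYMGGIRADFMQIEECINMYRMCPYLAGCIKDKPM
>pfam07724_seed6
NGSRFWLLVRWQFDACAHCKSIPAKIEPTCCIQRGNEFMQGSYFDVYMGGIRKDFMQIEKCINMYHMCNYTAGCIKDKPM
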