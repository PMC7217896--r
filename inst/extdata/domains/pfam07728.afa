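>pfam07728_seed1
WHVMGPHYNNVRFTRRDFWWNAANMIPQMPEQGVNSNTCWRWPEERYEWWCHDWLKFYPQVIAIQHKMKGPTQPWLGQSA
>pfam07728_seed2
WHVMGPHYNVVRFTRRDFWWNAMNWYPQMPEQGVNSNTCWRWPEERYETWPRDWLKFYNQVIMIQHNMKGPTQPWLGQSA
>pfam07728_seed3
WHVMGSHYNVDRKCRRDFWWNAANMYPQMPEQGVNSNMCWRWPNERYETWFHMWLKFYPQVIAIQHNMKGPTQPWLWQSA
>pfam07728_seed4
WHVIGPHQNVVRFTRPDFWWNAANMYMQMPEQGVNVTTCWRWPEERYETWPHDWWKFYPQVIAIQHNMKGPTQPWLGGSA
>pfam07728_seed5
WHVMGPIYNVVEFSRRDFWWNAAHMYPQMPEQGVNSMTCWRWPEERYERWPFGWLKFEPQVIFIQHNMKGPTQPWLGQSA
>pfam07728_seed6
WHVMGPHYAVVRFTLRDFWWNAANMYPQMPEQGVNSNTCWRWPFERYETWPHDWLKFYPQVIAIQSNMKGPMQPWLGADA
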