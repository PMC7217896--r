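>pfam10431_seed1
PKKCQDRALMQVPWIQEQTQWHFYRNTEQWHVKHMDIFMEQGCDLSRTMDGLQSEAIQAPDHEAVINTHNAMDSSAGPRS
>pfam10431_seed2
FKTCQDRALMQVPWIQETYQWTFYRNTEQWHVKHMDIFMEQGCDLSLTMDGLQGEAIQAPDGEAVINTPNAMDSEAMPRS
>pfam10431_seed3
AKTCKDRALMQVPWIQETEQWTFYRNTEQWHVKHMEIFMEAGCDLSRTMDGLQYEWIQAPEHEAVINTHNAMDSSAGPRS
>pfam10431_seed4
PKTCQDMALMGVPWIQEPYLWTFYRNTEQWHVKHMDIFMEFGCDLYRTMLGIQGEADQAPDHEAVINTHNAMDSYAGPRS
>pfam10431_seed5
PKTCQDRALMQVPWIQETCFWTFYRNTEQSHVKHMDVFMWQGCDLSRTMDGLQGEAIQAPDHEAVINTHNAMDSSAGPRS
>pfam10431_seed6
PSTCQDRALMQVPWIQETYQWCFYRNTEQWHVKHMDIFMEQGCDLSRTMDGLQGEAIQAPDHEAVINTHNWMDSSAGPRS
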