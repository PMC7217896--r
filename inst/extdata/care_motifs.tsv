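name	pattern	category
HSE	GAANNTTC	stress
ABRE	ACGTGKC	hormone
CAAT-box	CCAAT	TF-binding
TATA-box	TATAWA	other
G-box	CACGTG	light
MYB	WAACCA	TF-binding
MYC	CANNTG	TF-binding
W-box	TTGACC	stress
GT1-motif	GRWAAW	light
ARE	TGGTTT	stress
LTR	CCGAAA	stress
Skn-1	GTCAT	tissue-specific
RY-element	CATGCA	tissue-specific
POLASIG1	AATAAA	polyadenylation
CGTCA-motif	CGTCA	hormone
circadian	CAANNNNATC	light
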