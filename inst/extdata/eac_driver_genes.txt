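TP53
NOTCH1
ARID1A
CNTNAP5
PIK3CA
SMARCA4
CDKN2A
FBXW7
SMAD4
STAG2
SEMA5A
MYO18B
KRAS
ACVR2A
PTEN
BAX
CTNNB1
SF3B1
TAF1
CCND2
ERBB3
KMT2D
PIK3R1
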