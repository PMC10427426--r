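gene	is_oncogene
TP53	FALSE
PIK3CA	TRUE
ERBB2	TRUE
MYC	TRUE
CCND1	TRUE
ESR1	TRUE
GATA3	FALSE
PTEN	FALSE
RB1	FALSE
BRCA1	FALSE
BRCA2	FALSE
AKT1	TRUE
CDH1	FALSE
MAP3K1	FALSE
ARID1A	FALSE
KMT2C	FALSE
NF1	FALSE
SLX4	FALSE
FGFR1	TRUE
EGFR	TRUE
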