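gene	winner	concordant	reciprocal
NPAS3	1	0	1
DACH1	4	1	0
FOXP2	2	0	0
EBF3	4	0	0
FOXP1	5	0	0
AUTS2	0	1	0
ZEB2	3	1	1
ZFPM2	0	1	0
SOX6	4	0	0
ESRRG	5	0	0
EBF1	0	3	2
PBX3	1	0	0
MEIS2	3	1	0
OLA1	4	0	0
EHBP1	2	0	0
DACH2	1	0	0
MEIS1	2	0	0
NBEA	5	0	0
POLA1	1	0	0
SATB1	5	0	0
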