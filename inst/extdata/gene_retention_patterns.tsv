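gene	n_ucnes	genome	a	b	c
NPAS3	53	fugu	6	0	0
NPAS3	53	tetraodon	1	0	1
DACH1	39	fugu	22	1	0
DACH1	39	medaka	21	2	0
DACH1	39	stickleback	16	3	0
DACH1	39	tetraodon	20	1	0
DACH1	39	zebrafish	18	6	0
FOXP2	38	fugu	29	2	0
FOXP2	38	tetraodon	27	1	1
EBF3	38	medaka	27	1	0
EBF3	38	stickleback	24	4	1
EBF3	38	tetraodon	28	0	0
EBF3	38	zebrafish	31	0	0
FOXP1	38	fugu	25	0	0
FOXP1	38	medaka	19	0	0
FOXP1	38	stickleback	22	0	0
FOXP1	38	tetraodon	24	0	0
FOXP1	38	zebrafish	24	0	0
AUTS2	34	zebrafish	15	4	0
ZEB2	27	fugu	22	0	0
ZEB2	27	medaka	15	0	0
ZEB2	27	stickleback	6	1	2
ZEB2	27	tetraodon	19	0	0
ZEB2	27	zebrafish	8	5	2
ZFPM2	25	zebrafish	14	7	0
SOX6	22	fugu	14	0	0
SOX6	22	medaka	13	2	0
SOX6	22	stickleback	14	1	0
SOX6	22	tetraodon	12	0	0
ESRRG	22	fugu	7	0	0
ESRRG	22	medaka	7	0	0
ESRRG	22	stickleback	8	0	0
ESRRG	22	tetraodon	5	0	0
ESRRG	22	zebrafish	17	0	0
EBF1	21	fugu	2	1	2
EBF1	21	medaka	4	0	2
EBF1	21	stickleback	3	2	0
EBF1	21	tetraodon	3	1	0
EBF1	21	zebrafish	5	5	0
PBX3	21	zebrafish	16	2	0
MEIS2	18	medaka	15	0	0
MEIS2	18	stickleback	13	3	0
MEIS2	18	tetraodon	14	1	0
MEIS2	18	zebrafish	7	3	0
OLA1	16	fugu	14	0	0
OLA1	16	medaka	13	1	0
OLA1	16	stickleback	14	0	0
OLA1	16	tetraodon	11	0	0
EHBP1	15	fugu	9	0	0
EHBP1	15	tetraodon	7	0	0
DACH2	12	zebrafish	9	0	0
MEIS1	12	fugu	8	0	0
MEIS1	12	zebrafish	9	0	0
NBEA	12	fugu	8	0	1
NBEA	12	medaka	8	0	1
NBEA	12	stickleback	8	0	1
NBEA	12	tetraodon	7	0	0
NBEA	12	zebrafish	5	0	0
POLA1	12	tetraodon	5	0	0
SATB1	10	fugu	5	0	0
SATB1	10	medaka	11	0	0
SATB1	10	stickleback	7	0	0
SATB1	10	tetraodon	5	0	0
SATB1	10	zebrafish	7	0	0
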