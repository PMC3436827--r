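cluster	n_ucnes	genome	a	b	c
ZEB2_cluster	134	fugu	67	0	0
ZEB2_cluster	134	medaka	47	0	0
ZEB2_cluster	134	stickleback	36	1	3
ZEB2_cluster	134	tetraodon	56	0	0
ZEB2_cluster	134	zebrafish	24	6	15
CCNE1_cluster	96	fugu	37	11	4
CCNE1_cluster	96	medaka	31	11	4
CCNE1_cluster	96	stickleback	39	15	3
CCNE1_cluster	96	tetraodon	13	8	18
CCNE1_cluster	96	zebrafish	59	4	0
EBF3_cluster	96	fugu	48	0	0
EBF3_cluster	96	medaka	48	0	0
EBF3_cluster	96	stickleback	45	2	0
EBF3_cluster	96	tetraodon	48	0	0
EBF3_cluster	96	zebrafish	34	2	26
BCL11A_cluster	92	fugu	19	6	1
BCL11A_cluster	92	medaka	24	7	0
BCL11A_cluster	92	stickleback	23	6	1
BCL11A_cluster	92	tetraodon	18	4	1
BCL11A_cluster	92	zebrafish	47	3	0
FOXP2_cluster	83	fugu	57	1	0
FOXP2_cluster	83	medaka	42	0	0
FOXP2_cluster	83	stickleback	59	0	0
FOXP2_cluster	83	tetraodon	53	0	1
FOXP2_cluster	83	zebrafish	43	0	24
ZFHX4_cluster	79	fugu	36	0	0
ZFHX4_cluster	79	medaka	35	0	0
ZFHX4_cluster	79	stickleback	37	0	0
ZFHX4_cluster	79	tetraodon	30	0	0
ZFHX4_cluster	79	zebrafish	58	0	0
DACH1_cluster	73	fugu	35	1	0
DACH1_cluster	73	medaka	32	1	0
DACH1_cluster	73	stickleback	29	1	0
DACH1_cluster	73	tetraodon	34	1	0
DACH1_cluster	73	zebrafish	29	6	0
ESRRG_cluster	72	fugu	18	0	0
ESRRG_cluster	72	medaka	19	0	0
ESRRG_cluster	72	stickleback	22	1	1
ESRRG_cluster	72	tetraodon	10	0	0
ESRRG_cluster	72	zebrafish	49	0	1
NPAS3_cluster	71	fugu	7	0	2
NPAS3_cluster	71	medaka	9	0	0
NPAS3_cluster	71	stickleback	1	0	0
NPAS3_cluster	71	tetraodon	6	0	0
NPAS3_cluster	71	zebrafish	39	0	0
MEIS2_cluster	67	fugu	51	0	0
MEIS2_cluster	67	medaka	46	2	0
MEIS2_cluster	67	stickleback	46	4	1
MEIS2_cluster	67	tetraodon	41	0	0
MEIS2_cluster	67	zebrafish	25	3	0
NR2F1_cluster	67	fugu	36	0	0
NR2F1_cluster	67	medaka	34	0	0
NR2F1_cluster	67	stickleback	39	0	0
NR2F1_cluster	67	tetraodon	32	0	0
NR2F1_cluster	67	zebrafish	40	0	0
IRX3_cluster	60	fugu	34	3	0
IRX3_cluster	60	medaka	37	0	0
IRX3_cluster	60	stickleback	41	0	0
IRX3_cluster	60	tetraodon	22	0	8
IRX3_cluster	60	zebrafish	34	3	0
ADK_cluster	60	fugu	15	22	8
ADK_cluster	60	medaka	17	20	6
ADK_cluster	60	stickleback	16	22	8
ADK_cluster	60	tetraodon	16	22	4
ADK_cluster	60	zebrafish	40	0	4
TSHZ1_cluster	59	fugu	12	12	6
TSHZ1_cluster	59	medaka	14	11	2
TSHZ1_cluster	59	stickleback	11	11	6
TSHZ1_cluster	59	tetraodon	9	8	12
TSHZ1_cluster	59	zebrafish	28	0	0
NR2F2_cluster	57	fugu	23	0	2
NR2F2_cluster	57	medaka	23	1	0
NR2F2_cluster	57	stickleback	26	1	0
NR2F2_cluster	57	tetraodon	24	0	0
NR2F2_cluster	57	zebrafish	35	0	0
FOXP1_cluster	49	fugu	30	0	0
FOXP1_cluster	49	medaka	23	0	0
FOXP1_cluster	49	stickleback	28	0	0
FOXP1_cluster	49	tetraodon	30	0	0
FOXP1_cluster	49	zebrafish	30	0	0
MEIS1_cluster	45	fugu	22	0	0
MEIS1_cluster	45	medaka	14	0	0
MEIS1_cluster	45	tetraodon	21	0	0
MEIS1_cluster	45	zebrafish	25	0	0
POU3F3_cluster	44	fugu	9	0	0
POU3F3_cluster	44	medaka	17	1	0
POU3F3_cluster	44	stickleback	2	0	2
POU3F3_cluster	44	tetraodon	3	0	0
POU3F3_cluster	44	zebrafish	23	1	0
FIGN_cluster	44	fugu	8	13	3
FIGN_cluster	44	medaka	10	9	4
FIGN_cluster	44	stickleback	13	10	3
FIGN_cluster	44	tetraodon	10	11	3
FIGN_cluster	44	zebrafish	17	2	0
BNC2_cluster	43	fugu	24	0	0
BNC2_cluster	43	medaka	26	0	0
BNC2_cluster	43	stickleback	25	0	0
BNC2_cluster	43	tetraodon	24	0	0
BNC2_cluster	43	zebrafish	17	0	0
POU3F2_cluster	42	fugu	8	1	0
POU3F2_cluster	42	medaka	8	0	0
POU3F2_cluster	42	stickleback	8	1	0
POU3F2_cluster	42	tetraodon	7	1	0
POU3F2_cluster	42	zebrafish	9	0	0
PBX3_cluster	42	fugu	32	0	0
PBX3_cluster	42	medaka	34	0	0
PBX3_cluster	42	stickleback	35	0	0
PBX3_cluster	42	tetraodon	30	0	0
PBX3_cluster	42	zebrafish	27	1	3
RUNX1T1_cluster	41	fugu	13	0	0
RUNX1T1_cluster	41	medaka	11	0	0
RUNX1T1_cluster	41	stickleback	12	0	0
RUNX1T1_cluster	41	tetraodon	9	0	0
RUNX1T1_cluster	41	zebrafish	17	0	0
LMO4_cluster	40	fugu	16	1	0
LMO4_cluster	40	medaka	15	0	0
LMO4_cluster	40	stickleback	17	1	0
LMO4_cluster	40	tetraodon	14	0	0
LMO4_cluster	40	zebrafish	18	3	0
ZNF521_cluster	40	fugu	21	0	0
ZNF521_cluster	40	medaka	19	0	0
ZNF521_cluster	40	stickleback	19	0	0
ZNF521_cluster	40	tetraodon	15	0	0
ZNF521_cluster	40	zebrafish	5	0	1
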