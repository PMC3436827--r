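cluster	winner	concordant	reciprocal	note
ZEB2_cluster	4	0	1	.
CCNE1_cluster	1	3	1	.
EBF3_cluster	4	0	1	.
BCL11A_cluster	1	4	0	.
FOXP2_cluster	4	0	1	.
ZFHX4_cluster	5	0	0	.
DACH1_cluster	5	0	0	.
ESRRG_cluster	5	0	0	.
NPAS3_cluster	4	0	1	.
MEIS2_cluster	5	0	0	.
NR2F1_cluster	5	0	0	.
IRX3_cluster	4	0	1	.
ADK_cluster	1	4	0	strict rule: max c/n = 8/45 < 0.2, so no species is reciprocal
TSHZ1_cluster	1	2	2	strict rule: fugu has c/n = 6/30 = 0.2 exactly, not > 0.2, so concordant
NR2F2_cluster	5	0	0	.
FOXP1_cluster	5	0	0	.
MEIS1_cluster	4	0	0	.
POU3F3_cluster	4	0	1	.
FIGN_cluster	1	4	0	.
BNC2_cluster	5	0	0	.
POU3F2_cluster	5	0	0	.
PBX3_cluster	5	0	0	.
RUNX1T1_cluster	5	0	0	.
LMO4_cluster	5	0	0	.
ZNF521_cluster	5	0	0	.
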