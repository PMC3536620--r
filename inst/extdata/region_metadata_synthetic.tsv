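abbreviation	index	subdivision
CA1-a	1	hippocampus
CA1-m	2	hippocampus
CA1-d	3	hippocampus
CA1-p	4	hippocampus
CA3	5	hippocampus
DG-up	6	hippocampus
DG-low	7	hippocampus
Cg-a	8	neocortex
Cg-p	9	neocortex
PrL	10	neocortex
IL	11	neocortex
M1	12	neocortex
M2	13	neocortex
S1BF	14	neocortex
S1FL	15	neocortex
S1HL	16	neocortex
S1Tr	17	neocortex
S2	18	neocortex
V1	19	neocortex
V2	20	neocortex
A1	21	neocortex
Ect	22	neocortex
PRh	23	neocortex
Ent-l	24	neocortex
Ent-m	25	neocortex
RSA	26	neocortex
RSG	27	neocortex
PtA	28	neocortex
TeA	29	neocortex
Ins	30	neocortex
Orb-l	31	neocortex
Orb-m	32	neocortex
Re	33	thalamus
AD	34	thalamus
AV	35	thalamus
AM	36	thalamus
LD	37	thalamus
MD	38	thalamus
C	39	thalamus
Hb	40	thalamus
PV	41	thalamus
PT	42	thalamus
Rh	43	thalamus
VPM	44	thalamus
VPL	45	thalamus
LP	46	thalamus
Po	47	thalamus
Sub	48	thalamus
LH	49	hypothalamus
SHy	50	hypothalamus
LPO	51	hypothalamus
MPA	52	hypothalamus
DM	53	hypothalamus
VMH	54	hypothalamus
AH	55	hypothalamus
PH	56	hypothalamus
MM	57	hypothalamus
SuM	58	hypothalamus
PVN	59	hypothalamus
BST	60	cerebral nuclei
AcbSh	61	cerebral nuclei
AcbC	62	cerebral nuclei
CPu-dm	63	cerebral nuclei
CPu-vl	64	cerebral nuclei
VP	65	cerebral nuclei
LSI	66	cerebral nuclei
LSV	67	cerebral nuclei
LSD	68	cerebral nuclei
MS	69	cerebral nuclei
La	70	cerebral nuclei
BLA	71	cerebral nuclei
BMA	72	cerebral nuclei
Ce	73	cerebral nuclei
MeA	74	cerebral nuclei
GP	75	cerebral nuclei
SI	76	cerebral nuclei
PAG	77	midbrain
VTA	78	midbrain
SNc	79	midbrain
SNr	80	midbrain
SC	81	midbrain
IC	82	midbrain
DR	83	midbrain
IP	84	midbrain
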