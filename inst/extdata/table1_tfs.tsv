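gene	connections	deg_connections	rank	p_value	eccentricity	closeness	in_healthy_network
FOSB	4	4	1.000	<1.00E-04	9	0.209	NO
JUN	2	2	1.000	<1.00E-04	11	0.151	NO
NR4A2	5	5	1.000	<1.00E-04	9	0.204	NO
OSR2	12	12	1.000	<1.00E-04	8	0.234	NO
ZBTB16	1	1	1.000	<1.00E-04	9	0.200	NO
EGR2	10	9	0.900	<1.00E-04	8	0.247	NO
NR4A3	9	8	0.889	<1.00E-04	8	0.249	NO
EBF1	162	143	0.883	<1.00E-04	7	0.294	YES
HEY2	24	21	0.875	<1.00E-04	8	0.266	NO
NR4A1	16	14	0.875	<1.00E-04	8	0.240	NO
PRRX1	30	26	0.867	<1.00E-04	7	0.289	NO
EGR1	13	11	0.846	<1.00E-04	9	0.217	YES
FOS	6	5	0.833	<1.00E-04	10	0.178	NO
JUNB	5	4	0.800	<1.00E-04	10	0.178	NO
MEOX2	75	60	0.800	<1.00E-04	7	0.303	NO
ZFPM2	133	106	0.797	<1.00E-04	7	0.296	NO
ERG	76	60	0.789	<1.00E-04	8	0.287	NO
TSHZ2	109	85	0.780	<1.00E-04	7	0.302	NO
FOXC1	27	21	0.778	<1.00E-04	8	0.268	NO
HLF	84	65	0.774	<1.00E-04	7	0.301	NO
MEIS2	133	100	0.752	<1.00E-04	8	0.305	NO
CREB5	32	24	0.750	<1.00E-04	8	0.278	NO
PRDM6	83	62	0.747	<1.00E-04	7	0.293	NO
GLIS2	79	58	0.734	<1.00E-04	7	0.302	NO
HAND2	138	101	0.732	<1.00E-04	7	0.289	NO
EGR3	11	8	0.727	<1.00E-04	8	0.263	NO
SOX18	40	29	0.725	<1.00E-04	7	0.274	NO
ZNF423	79	57	0.722	<1.00E-04	8	0.303	YES
PHOX2B	60	42	0.700	<1.00E-04	8	0.275	YES
KLF7	133	92	0.692	<1.00E-04	7	0.313	NO
GLI3	217	150	0.691	<1.00E-04	7	0.325	NO
MEIS1	113	77	0.681	<1.00E-04	8	0.301	YES
KLF2	15	10	0.667	<1.00E-04	8	0.261	YES
TSHZ3	80	52	0.650	<1.00E-04	8	0.302	YES
NKX2-3	75	47	0.627	<1.00E-04	8	0.290	NO
BNC2	252	148	0.587	<1.00E-04	7	0.334	NO
PITX2	26	15	0.577	<1.00E-04	9	0.244	YES
PRDM8	70	40	0.571	<1.00E-04	7	0.304	YES
NR2F2	141	78	0.553	<1.00E-04	7	0.334	YES
TSC22D3	29	16	0.552	<1.00E-04	7	0.282	NO
PBX3	186	102	0.548	<1.00E-04	7	0.337	YES
ZEB1	264	139	0.527	<1.00E-04	7	0.343	YES
FOXF1	62	31	0.500	<1.00E-04	7	0.312	YES
ZNF532	110	52	0.473	<1.00E-04	7	0.326	YES
CAMTA1	68	30	0.441	<1.00E-04	7	0.318	YES
JAZF1	172	74	0.430	<1.00E-04	7	0.334	NO
AFF3	31	11	0.355	<1.00E-04	7	0.295	YES
NFIC	131	43	0.328	<1.00E-04	7	0.339	YES
ZEB2	74	24	0.324	<1.00E-04	7	0.324	YES
TCF4	408	129	0.316	<1.00E-04	6	0.371	YES
BCL6	36	11	0.306	<1.00E-04	7	0.309	NO
NR1H4	77	22	0.286	<1.00E-04	8	0.282	YES
MAFB	125	23	0.184	<1.00E-04	6	0.313	YES
HOXB13	93	14	0.151	<1.00E-04	8	0.264	NO
ATF3	4	3	0.750	0.0003	10	0.184	NO
ZBTB20	149	13	0.087	0.0183982	7	0.356	YES
THRB	12	2	0.167	0.0986901	8	0.259	YES
HOXB6	2	0	0.000	1	8	0.227	YES
IFI16	5	0	0.000	1	7	0.247	YES
NEUROD1	12	0	0.000	1	8	0.236	NO
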