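secreted_gene	secreted_tissue	receptor_gene	receptor_tissue
SLIT2	A	ITGA1	T
SLIT2	A	ROBO2	T
SLIT2	A	ROBO1	T
SLIT3	A	ROBO2	T
SLIT3	A	ROBO1	T
SLIT2	A	ROBO4	T
FGF7	A	FGFR4	T
PTN	A	SDC3	T
TIMP2	A	MMP14	T
MMP3	A	MMP14	T
SPOCK1	A	MMP14	T
ISG15	A	NEDD4	T
VIP	A	MME	T
MYOC	A	CD81	T
RELN	A	LRP8	T
CLU	A	LRP8	T
SERPING1	A	SELE	T
CYR61	A	ITGA1	T
FIGF	A	ITGA9	T
HBEGF	A	CD82	T
CXCL12	A	CXCR4	T
CFH	A	IGDCC4	T
CFD	A	IGDCC4	T
IL8	T	DARC	A
MIF	T	CALD1	A
PLA1A	T	CALD1	A
PF4	T	LDLR	A
WNT5A	T	ROR2	A
REG3A	T	SDC2	A
SPARC	T	SDC2	A
KAL1	T	SDC2	A
PF4	T	SDC2	A
FN1	T	SDC2	A
FN1	T	ITGA5	A
FN1	T	IGDCC4	A
FN1	T	CD36	A
FN1	T	PECAM1	A
TNC	T	CNTN1	A
TNC	T	ITGA5	A
TNC	T	ITGA9	A
COL18A1	T	ITGA5	A
SFRP2	T	ITGA5	A
SPP1	T	ITGA5	A
SPP1	T	ITGA9	A
AGT	T	AGTR1	A
AGT	T	CTSG	A
APOC2	T	IGDCC4	A
PPBP	T	IGDCC4	A
PPBP	T	CTSG	A
TAC1	T	TACR2	A
CXCL5	T	DARC	A
CCL2	T	DARC	A
C4A	T	IGDCC4	A
IGHG1	T	IGDCC4	A
PCSK9	T	LDLR	A
MMP9	T	ITGA5	A
MMP9	T	RECK	A
VEGFA	T	NRP2	A
PGF	T	NRP2	A
ADAM12	T	ITGA9	A
COL4A1	T	CD93	A
COL4A1	T	CD36	A
COL1A1	T	DDR2	A
COL1A1	T	ITGA5	A
COL1A1	T	CD93	A
COL1A1	T	CD36	A
COL1A2	T	CD93	A
COL1A2	T	CD36	A
COL3A1	T	DDR2	A
COL6A1	T	CD36	A
COL6A3	T	ITGA5	A
COL4A2	T	CD93	A
COL4A2	T	CD36	A
LAMA4	T	ITGA5	A
CFB	T	IGDCC4	A
SEMA3F	T	NRP2	A
EFNA3	T	EPHA3	A
C3	T	CTSG	A
INHBA	T	TGFBR3	A
LIF	T	LIFR	A
FN1	T	FGFR1	A
IGHG1	T	FGFR1	A
ELN	T	FGFR1	A
C3	T	FGFR1	A
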