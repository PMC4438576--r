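gene	agents
MMP12	AZD1236
SHH	Erismodegib, Vismodegib
IL2RB	Denileukin diftitox
LCK	Dasatinib, Pazopanib
EPHA2	Dasatinib, Regorafenib
AREG	Cetuximab
PIK3CD	Idelalisib
IL6R	Siltuximab
MMP9	AZD1236
EPCAM	Tucotuzumab celmoleukin
SRC	Bosutinib, Dasatinib
MUC1	HuHMFG1
ERBB3	Lapatinib
TNFSF11	Denosumab
MAPK14	Regorafenib
PTGS2	Lenalidomide
RRAS	Sorafenib
PSMB1	Carfilzomib
EGFR	Cetuximab, Erlotinib, Gefitinib, Lapatinib
CD52	Alemtuzumab
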