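gene	gene_name	avg_percentile	n_above	agents	fold	p
MMP12	matrix metallopeptidase 12	99.4	15	AZD1236	819.7	3.0e-49
SHH	sonic hedgehog homolog	98.9	15	Erismodegib, Vismodegib	96.9	1.5e-48
IL2RB	interleukin 2 receptor, beta	96.7	15	Denileukin diftitox	12.4	4.87e-23
LCK	lymphocyte-specific protein tyrosine kinase	95.2	15	Dasatinib, Pazopanib	5.5	8.2e-16
EPHA2	EPH receptor A2	95.1	15	Dasatinib, Regorafenib	16.6	6.8e-16
AREG	amphiregulin	93.9	15	Cetuximab	20.9	4.8e-17
PIK3CD	phosphoinositide-3-kinase, catalytic, delta	93.8	15	Idelalisib	6.79	3.55e-10
IL6R	interleukin 6 receptor	91.9	15	Siltuximab	6.13	7.06e-8
MMP9	matrix metallopeptidase 9	91.6	15	AZD1236	41.0	9.8e-14
EPCAM	epithelial cell adhesion molecule	90.7	15	Tucotuzumab celmoleukin	87.4	2.01e-11
SRC	v-src sarcoma viral oncogene homolog	89.9	15	Bosutinib, Dasatinib	2.5	3.7e-7
MUC1	mucin 1	89.3	15	HuHMFG1	6.30	1.27e-7
ERBB3	v-erb-b2 erythroblastic leukemia viral oncogene homolog 3	86.7	15	Lapatinib	22.8	4.2e-8
TNFSF11	tumor necrosis factor (ligand) superfamily, member 11	91.7	14	Denosumab	5.17	4.28e-8
MAPK14	mitogen-activated protein kinase 14	91.3	14	Regorafenib	2.65	2.49e-8
PTGS2	prostaglandin-endoperoxide synthase 2	85.6	14	Lenalidomide	10.5	9.23e-7
RRAS	related RAS viral (r-ras) oncogene homolog	85.4	14	Sorafenib	3.61	2.32e-5
PSMB1	proteasome subunit, beta type, 1	83.8	14	Carfilzomib	1.45	5.85e-5
EGFR	epidermal growth factor receptor	83.4	14	Cetuximab, Erlotinib, Gefitinib, Lapatinib	7.6	6.0e-5
CD52	CD52 molecule	86.3	13	Alemtuzumab	8.85	4.51e-12
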