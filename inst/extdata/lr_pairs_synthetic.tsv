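pair	ligand_genes	receptor_genes
EFNA1_EPHA2	EFNA1	EPHA2
SAA1_FPR2	SAA1	FPR2
APP_FPR2	APP	FPR2
CXCL14_CXCR4	CXCL14	CXCR4
APP_TREM2	APP	TREM2
HLA-F_VSIR	HLA-F	VSIR
PTGES_PTGER4	PTGES	PTGER4
IL1B_IL1R	IL1B	IL1R1,IL1RAP
CXCL9_CXCR3	CXCL9	CXCR3
TNF_TNFRSF1A	TNF	TNFRSF1A
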