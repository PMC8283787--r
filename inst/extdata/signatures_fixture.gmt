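CD8_T_effector	TME_cells	CD8A	CD8B	GZMA	GZMB	PRF1	IFNG	CXCL9	CXCL10
NK_cells	TME_cells	KLRD1	NKG7	GNLY	KIR2DL1	KIR2DL3	NCR1
Macrophage_M1	TME_cells	NOS2	IL12A	IL12B	CXCL11	TNF	IL1B
Macrophage_M2	TME_cells	CD163	MRC1	MSR1	IL10	CCL22	ARG1
B_cells	TME_cells	CD19	MS4A1	CD79A	CD79B	IGHM	BLK
Fibroblasts_CAF	TME_cells	FAP	PDGFRB	ACTA2	COL1A1	COL1A2	PDPN
Immune_checkpoint	immunophenotype	PDCD1	CD274	CTLA4	LAG3	HAVCR2	TIGIT	BTLA
Antigen_processing	immunophenotype	TAP1	TAP2	B2M	HLA-A	HLA-B	HLA-C	PSMB9
IFN_gamma_response	immunophenotype	STAT1	IRF1	IDO1	GBP1	GBP2	CXCL9
Glycolysis	metabolism	HK2	PFKM	PKM	LDHA	SLC2A1	ENO1
Hypoxia	tumor_intrinsic	HIF1A	VEGFA	CA9	SLC2A1	ADM	NDRG1
EMT	tumor_intrinsic	SNAI1	SNAI2	TWIST1	VIM	ZEB1	ZEB2	CDH2
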