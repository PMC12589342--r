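TOY_EPITHELIAL_IDENTITY	synthetic_toy_pathway	EPCAM	KRT19	KRT18	KRT8	SFTPC	SFTPB	SFTPA1	GENE00233	GENE00221	GENE00372	GENE00273	GENE00199
TOY_AIRWAY_SECRETION	synthetic_toy_pathway	SCGB1A1	SCGB3A2	BPIFB1	FOXJ1	TPPP3	PIFO	GENE00126	GENE00124	GENE00083	GENE00008	GENE00087
TOY_ENDOTHELIUM	synthetic_toy_pathway	PECAM1	CLDN5	VWF	GENE00136	GENE00281	GENE00061	GENE00244	GENE00271
TOY_ECM_ORGANIZATION	synthetic_toy_pathway	COL1A1	COL1A2	DCN	GENE00266	GENE00090	GENE00142	GENE00010	GENE00067
TOY_BCELL_RECEPTOR	synthetic_toy_pathway	MS4A1	CD79A	CD79B	MZB1	IGHG1	JCHAIN	GENE00001	GENE00262	GENE00077	GENE00339	GENE00033
TOY_TCELL_ACTIVATION	synthetic_toy_pathway	CD3D	CD3E	TRAC	GENE00282	GENE00225	GENE00358	GENE00266	GENE00238
TOY_GRANULOCYTE_RESPONSE	synthetic_toy_pathway	FCGR3B	CSF3R	CXCR2	TPSAB1	TPSB2	CPA3	GENE00350	GENE00261	GENE00036	GENE00222	GENE00112
TOY_MYELOID_CORE	synthetic_toy_pathway	LYZ	AIF1	TYROBP	FCER1G	CD68	MARCO	C1QA	C1QB	GENE00240	GENE00197	GENE00217	GENE00379	GENE00241
TOY_MONOCYTE_RECRUITMENT	synthetic_toy_pathway	FCN1	S100A8	S100A9	VCAN	GENE00361	GENE00352	GENE00270	GENE00313	GENE00097
TOY_DC_MATURATION	synthetic_toy_pathway	LAMP3	FSCN1	CCL19	CLEC9A	XCR1	BATF3	CD1C	FCER1A	CLEC10A	LILRA4	CLEC4C	IRF7	GENE00352	GENE00239	GENE00317	GENE00104	GENE00290
TOY_INTERFERON_RESPONSE	synthetic_toy_pathway	CXCL9	CXCL10	CXCL11	GBP1	IRF7	GENE00282	GENE00387	GENE00361	GENE00052	GENE00194
TOY_INFLAMMATORY_CYTOKINES	synthetic_toy_pathway	IL1B	TNF	IL12B	NOS2	CD80	CD86	GENE00059	GENE00300	GENE00204	GENE00202	GENE00305
TOY_ALTERNATIVE_ACTIVATION	synthetic_toy_pathway	MRC1	MSR1	FABP4	CD163	CCL22	CCL17	IL10	TGFB1	GENE00199	GENE00260	GENE00252	GENE00057	GENE00322
TOY_IRON_RECYCLING	synthetic_toy_pathway	SELENOP	SLC40A1	STAB1	F13A1	GENE00012	GENE00145	GENE00314	GENE00390	GENE00131
TOY_TISSUE_REMODELING	synthetic_toy_pathway	SPP1	MMP9	CHI3L1	VEGFA	GENE00300	GENE00029	GENE00368	GENE00280	GENE00296
TOY_PROLIFERATION	synthetic_toy_pathway	STMN1	MKI67	TOP2A	TUBA1B	GENE00095	GENE00190	GENE00338	GENE00170	GENE00364
TOY_AZUROPHIL_GRANULE	synthetic_toy_pathway	AZU1	ELANE	PRTN3	MPO	GENE00358	GENE00372	GENE00355	GENE00218	GENE00064
TOY_CHEMOTAXIS_AXIS	synthetic_toy_pathway	CXCL14	CXCR4	SAA1	FPR2	CXCR3	GENE00241	GENE00170	GENE00111	GENE00062	GENE00228
TOY_EPHRIN_SIGNALING	synthetic_toy_pathway	EFNA1	EPHA2	GENE00137	GENE00333	GENE00037	GENE00364	GENE00198
TOY_CHECKPOINT_TOLERANCE	synthetic_toy_pathway	HLA-F	VSIR	TREM2	APP	GENE00365	GENE00158	GENE00260	GENE00290	GENE00164
TOY_PROSTAGLANDIN_PATHWAY	synthetic_toy_pathway	PTGES	PTGER4	GENE00352	GENE00128	GENE00260	GENE00185	GENE00035
TOY_RANDOM_MODULE_01	synthetic_toy_pathway	GENE00381	GENE00099	GENE00244	GENE00228	GENE00080	GENE00238	GENE00309	GENE00007	GENE00292	GENE00399	GENE00029	GENE00219	GENE00259	GENE00180	GENE00214
TOY_RANDOM_MODULE_02	synthetic_toy_pathway	GENE00193	GENE00141	GENE00085	GENE00363	GENE00374	GENE00250	GENE00069	GENE00176	GENE00299	GENE00263	GENE00355	GENE00248	GENE00065	GENE00228	GENE00259	GENE00360
TOY_RANDOM_MODULE_03	synthetic_toy_pathway	GENE00308	GENE00038	GENE00166	GENE00035	GENE00072	GENE00197	GENE00007	GENE00301	GENE00190	GENE00272	GENE00054	GENE00135	GENE00087	GENE00076	GENE00243	GENE00194	GENE00390	GENE00010	GENE00302	GENE00342
TOY_RANDOM_MODULE_04	synthetic_toy_pathway	GENE00187	GENE00198	GENE00056	GENE00013	GENE00326	GENE00244	GENE00160	GENE00234	GENE00286	GENE00190	GENE00243	GENE00205	GENE00240	GENE00012
TOY_RANDOM_MODULE_05	synthetic_toy_pathway	GENE00171	GENE00242	GENE00201	GENE00100	GENE00044	GENE00248	GENE00021	GENE00179	GENE00050	GENE00300	GENE00197	GENE00128	GENE00101	GENE00228	GENE00238	GENE00330	GENE00178	GENE00204	GENE00215	GENE00150
TOY_RANDOM_MODULE_06	synthetic_toy_pathway	GENE00236	GENE00331	GENE00150	GENE00122	GENE00366	GENE00003	GENE00288	GENE00220	GENE00320	GENE00390	GENE00090
TOY_RANDOM_MODULE_07	synthetic_toy_pathway	GENE00398	GENE00132	GENE00261	GENE00256	GENE00025	GENE00267	GENE00387	GENE00103	GENE00069	GENE00382	GENE00350	GENE00360	GENE00112	GENE00108
TOY_RANDOM_MODULE_08	synthetic_toy_pathway	GENE00238	GENE00178	GENE00196	GENE00261	GENE00019	GENE00214	GENE00208	GENE00041	GENE00240	GENE00201	GENE00195	GENE00107	GENE00193
TOY_RANDOM_MODULE_09	synthetic_toy_pathway	GENE00194	GENE00206	GENE00358	GENE00052	GENE00053	GENE00048	GENE00160	GENE00095	GENE00133	GENE00230	GENE00368	GENE00268
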