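TGF_BETA_SIGNALLING	demo set, illustrative members	TGFBR2	APC	CDH1	CREBBP	EP300	SMAD3	SMAD4	TSC2
TGF_BETA_SMAD_DEPENDENT	demo set, illustrative members	TGFBR2	SMAD3	FBXW7
P53_PATHWAY	demo set, illustrative members	TP53	EP300	CDKN2A	MYC
P21_CELL_CYCLE_INHIBITOR	demo set, illustrative members	TP53	CDKN1A
E_CADHERIN_SIGNALLING	demo set, illustrative members	CDH1	CTNNB1
L1CAM_INTERACTIONS	demo set, illustrative members	ANK2	CLTC	LAMC1	DCX	KCNQ3	KIAA1598	NRP2	SCN2A	SPTBN1	ITGA9	SPTBN2
AXON_GUIDANCE	demo set, illustrative members	ANK2	ARHGEF12	CLTC	GSK3B	LAMC1	MYH9	PLXNA2	RGMA	RGMB	RND1	SEMA6A	SRGAP2	CLASP1	CREB1	DCX	ENAH	KCNQ3	KRAS	MET	NRP2	PAK7	PITPNA	ROCK1	SCN2A	SEMA6D	SPTBN1	SRGAP1	COL1A2	COL3A1	ITGA9	SPTBN2
DNA_DAMAGE_REPAIR	demo set, illustrative members	EP300	ERCC4	TP53
PAIN_PERCEPTION	demo set, illustrative members	NTRK1	TNF
DICER1_PATHWAY	demo set, illustrative members	DICER1
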