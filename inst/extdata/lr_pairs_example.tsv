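ligand	receptor
FLT3	FLT3LG
LY9	LY9
CD5	CD5
CD40LG	ITGA2B/ITGB3
APP	CD74
TNFRSF17	TNFSF13
FCER2	ITGAV/ITGB3
CD274	PDCD1
CD80	CTLA4
CD86	CTLA4
CXCL16	CXCR6
CXCL9	CXCR3
TGFB1	TGFBR1/TGFBR2
IL2	IL2RA/IL2RB/IL2RG
CCL5	CCR5
TNFSF13B	TNFRSF13B
ICOSLG	ICOS
LGALS9	HAVCR2
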