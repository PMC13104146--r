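myCAF	synthetic stand-in marker list	FAP	ACTA2	POSTN	MMP9	MMP12	COL1A1
iCAF	synthetic stand-in marker list	IL6	CXCL12	CXCL14	PDGFRA
apCAF	synthetic stand-in marker list	CD74	HLA-DRA	HLA-DRB1
vCAF	synthetic stand-in marker list	RGS5	NOTCH3	PDGFRB
mesCAF	synthetic stand-in marker list	MSLN	UPK3B	CALB2
adipoCAF	synthetic stand-in marker list	APOD	CFD	PLIN2
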