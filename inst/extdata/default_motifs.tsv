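ASTC	SXWKQCXFNAVSCFa	C
ASTB	WX(6)Wa	C
SK	[YF]G[HMF][MLF][RK]Fa	C
TRP	FXGXRa	C
SIF	SIFa	C
ASTA	[YF]XFG[LI]a	C
Orco	NFDEIDR	N
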