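mechanosensor	target	direction	citation
Connexin	ATP	up	connexin hemichannel ATP release
TRPV4	Ca2	up	TRPV4 calcium influx
TRPV4	COL2a	up	TRPV4 anabolic response
TRPV4	Agg	up	TRPV4 anabolic response
TRPV4	NO	down	TRPV4 suppression of nitric oxide
TRPV4	ADAMTS5	down	TRPV4 suppression of aggrecanase
TRPV4	IL1b	down	TRPV4 suppression of IL-1beta
a5b1	Agg	up	alpha5beta1 cyclic strain anabolism
aVb3	Agg	down	alphaVbeta3 catabolic signalling
PIEZO	Ca2	up	PIEZO calcium influx
PIEZO	actin	down	PIEZO-driven actin depolymerization
PTCH	GLIr	up	hedgehog pathway activation
PTCH	Ihh	up	hedgehog pathway activation
PTHrP	CITED2	up	PTHrP chondroprotection
PTHrP	Agg	up	PTHrP chondroprotection
PTHrP	MMP1	down	PTHrP protease suppression
PTHrP	MMP3	down	PTHrP protease suppression
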