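node,category,h,gamma
TRPV4,mechanosensor,10,1
PIEZO,mechanosensor,10,1
PTCH,mechanosensor,10,1
Connexin,mechanosensor,10,1
TLR,mechanosensor,10,1
a5b1,mechanosensor,10,1
aVb3,mechanosensor,10,1
aVb5,mechanosensor,10,1
Ca2,second_messenger,10,1
ROS,second_messenger,10,1
NO,second_messenger,10,1
ATP,second_messenger,10,1
SP,second_messenger,10,1
NFkB,transcription_factor,10,1
Sox9,transcription_factor,10,1
CITED2,transcription_factor,10,1
FOXO,transcription_factor,10,1
Runx2,transcription_factor,10,1
HIF2a,transcription_factor,10,1
AP1,transcription_factor,10,1
bcatenin,transcription_factor,10,1
GLIr,transcription_factor,10,1
IL1b,pro_inflammatory,10,1
TNFa,pro_inflammatory,10,1
IL6,pro_inflammatory,10,1
IL8,pro_inflammatory,10,1
IL17,pro_inflammatory,10,1
IL18,pro_inflammatory,10,1
IL4,anti_inflammatory,10,1
IL10,anti_inflammatory,10,1
IL13,anti_inflammatory,10,1
IL1Ra,anti_inflammatory,10,1
TGFb,growth_factor,10,1
IGF1,growth_factor,10,1
BMP2,growth_factor,10,1
Agg,structural_protein,10,1
COL2a,structural_protein,10,1
FN,structural_protein,10,1
actin,structural_protein,10,1
ADAMTS4,degrading_enzyme,10,1
ADAMTS5,degrading_enzyme,10,1
MMP1,degrading_enzyme,10,1
MMP3,degrading_enzyme,10,1
MMP13,degrading_enzyme,10,1
MMP14,degrading_enzyme,10,1
RGD,other,10,1
Wnt,other,10,1
CD40,other,10,1
PGE2,other,10,1
VEGF,other,10,1
Ihh,other,10,1
PTHrP,other,10,1
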