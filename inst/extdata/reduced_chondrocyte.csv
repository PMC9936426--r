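# reduced figure-derived chondrocyte mechano-inflammatory network (synthetic
# stand-in for the full curated 118-node interactome, which is published only
# in supplementary material not shipped here). Edges are assembled strictly
# from pathway statements in the source description: integrin alpha5beta1 ->
# substance P -> IL-4 axis; TRPV4/PIEZO calcium routes; PIEZO-driven ROS and
# actin depolymerization; fibronectin-integrin-actin with the RGD switch
# (see reduced_chondrocyte.rules.json); NF-kB inflammatory core with cytokine
# feedback; Wnt/beta-catenin and TLR inputs; hedgehog (PTCH/GLIr/Ihh) and
# PTHrP routes; degrading enzymes attacking Agg/COL2-alpha/fibronectin and
# releasing RGD fragments; anti-inflammatory and growth-factor controls.
source,target,sign,weight
FN,a5b1,activates,1
FN,aVb3,activates,1
a5b1,actin,activates,1
aVb3,actin,activates,1
a5b1,SP,activates,1
SP,IL4,activates,1
IL4,Agg,activates,1
IL4,IL1b,inhibits,1
IL4,MMP3,inhibits,1
IL4,AP1,inhibits,1
TRPV4,Ca2,activates,1
PIEZO,Ca2,activates,1
Ca2,Sox9,activates,1
PIEZO,ROS,activates,1
ROS,actin,inhibits,1
ROS,NFkB,activates,1
actin,Sox9,activates,1
TGFb,Sox9,activates,1
NFkB,Sox9,inhibits,1
Sox9,COL2a,activates,1
Sox9,Agg,activates,1
TGFb,FOXO,activates,1
NFkB,FOXO,inhibits,1
PTHrP,CITED2,activates,1
NFkB,CITED2,inhibits,1
PTHrP,Agg,activates,1
PTHrP,MMP1,inhibits,1
PTHrP,MMP3,inhibits,1
IL1b,NFkB,activates,1
TNFa,NFkB,activates,1
IL6,NFkB,activates,1
IL17,NFkB,activates,1
IL18,NFkB,activates,1
bcatenin,NFkB,activates,1
TLR,NFkB,activates,1
TLR,CD40,activates,1
aVb5,NFkB,activates,1
Wnt,bcatenin,activates,1
RGD,TLR,activates,1
NFkB,IL1b,activates,1
NFkB,TNFa,activates,1
NFkB,IL6,activates,1
NFkB,IL8,activates,1
IL1b,AP1,activates,1
TNFa,AP1,activates,1
NFkB,MMP1,activates,1
NFkB,MMP3,activates,1
NFkB,MMP13,activates,1
NFkB,MMP14,activates,1
NFkB,ADAMTS4,activates,1
NFkB,ADAMTS5,activates,1
AP1,MMP1,activates,1
AP1,MMP13,activates,1
NFkB,HIF2a,activates,1
NFkB,Runx2,activates,1
NFkB,BMP2,activates,1
BMP2,Runx2,activates,1
Ihh,Runx2,activates,1
NFkB,NO,activates,1
NFkB,PGE2,activates,1
NFkB,VEGF,activates,1
HIF2a,VEGF,activates,1
ADAMTS4,Agg,inhibits,1
ADAMTS5,Agg,inhibits,1
MMP1,COL2a,inhibits,1
MMP3,COL2a,inhibits,1
MMP13,COL2a,inhibits,1
MMP14,COL2a,inhibits,1
MMP3,FN,inhibits,1
MMP13,FN,inhibits,1
MMP3,RGD,activates,1
MMP13,RGD,activates,1
NFkB,TGFb,inhibits,1
NFkB,IGF1,inhibits,1
NFkB,IL4,inhibits,1
IL10,IL1b,inhibits,1
IL10,TNFa,inhibits,1
IL13,IL1b,inhibits,1
IL1Ra,IL1b,inhibits,1
IGF1,Agg,activates,1
IGF1,COL2a,activates,1
TGFb,COL2a,activates,1
PTCH,GLIr,activates,1
PTCH,Ihh,activates,1
Connexin,ATP,activates,1
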