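# T-LGL leukemia survival signalling network, 60 nodes.
# Transcription of the Boolean model of cytotoxic T cell signalling in
# T cell large granular lymphocyte leukemia (Zhang et al. 2008, PNAS
# 105:16308; 60-node reduction of Saadatpour et al. 2011, PLoS Comput Biol
# 7:e1002267).  The supplementary rule listing was not available verbatim;
# this file is a reconstruction from the published model descriptions,
# validated against the published stable-motif analysis of the network
# (motif inventory, attractor count, control and blocking target sets,
# baseline attractor probabilities).  See the package vignette.
# Inputs (fix via environment): Stimuli=ON, IL15=ON, PDGF=ON,
#                               Stimuli2=OFF, CD45=OFF, TAX=OFF.
CTLA4* = TCR
TCR* = Stimuli and not CTLA4
PLCG1* = GRB2 or PDGFR or TCR
GRB2* = IL2RB or ZAP70
ZAP70* = LCK and not FYN
LCK* = CD45 and (TCR or IL2RB) and not ZAP70
FYN* = TCR or IL2RB
Cytoskeleton_signaling* = FYN
RAS* = (GRB2 or PLCG1) and not GAP
GAP* = (RAS or (PDGFR and GAP)) and not (IL15 or IL2)
MEK* = RAS
ERK* = MEK and PI3K
PI3K* = PDGFR or RAS
NFKB* = TPL2 or PI3K
NFAT* = PI3K
TPL2* = TAX or (PI3K and TNF)
TNF* = NFKB
TRADD* = TNF
A20* = TNF
RANTES* = NFKB
IL2* = (NFKB or STAT3 or NFAT) and not TBET
IL2RB* = IL2RBT and (IL2 or IL15)
IL2RBT* = ERK and TBET
IL2RAT* = IL2 and (STAT3 or NFKB)
IL2RA* = IL2 and IL2RAT
JAK* = (IL2RA or IL2RB or RANTES or IFNG) and not (SOCS or CD45)
SOCS* = JAK and not (IL2 or IL15)
STAT3* = JAK
P27* = STAT3
Proliferation* = STAT3 and not P27
TBET* = JAK or TBET
CREB* = ERK and IFNG
IFNGT* = TBET or STAT3 or NFAT
IFNG* = ((IL2 or IL15 or Stimuli) and IFNGT) and not (SMAD or P2)
P2* = (IFNG or P2) and not Stimuli2
GZMB* = (CREB and IFNG) or TBET
FasL* = STAT3 or NFKB or NFAT or ERK
FasT* = NFKB
sFas* = S1P
Fas* = FasL and (FasT or Ceramide) and not sFas
DISC* = FasT and ((Fas and IL2) or Ceramide or (Fas and not FLIP))
Caspase* = (((TRADD or GZMB) and BID) or DISC) and not IAP
FLIP* = (NFKB or (CREB and IFNG)) and not DISC
BID* = (Caspase or GZMB) and not (BclxL or MCL1)
IAP* = NFKB and not BID
BclxL* = (NFKB or STAT3) and not (BID or GZMB)
MCL1* = (IL2RB and STAT3 and NFKB and PI3K) and not DISC
Apoptosis* = Caspase
GPCR* = S1P
SMAD* = GPCR
SPHK1* = PDGFR
S1P* = SPHK1 and not Ceramide
PDGFR* = PDGF and S1P
Ceramide* = Fas and not S1P
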