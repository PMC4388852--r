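# Helper T cell differentiation network, 55 nodes.
# Reconstruction of the logical model of helper T cell activation and
# differentiation (Naldi et al. 2010, PLoS Comput Biol 6:e1000912) under
# the environmental condition APC=ON, TGFB_e=ON, IL2_e=ON (all other
# external cytokines absent).  The supplementary Boolean rule listing was
# not available verbatim; this file is a reconstruction from the published
# model descriptions, validated against the published stable-motif control
# targets for the Th1/Th2/Th17/Treg subtypes and the published baseline
# attractor probabilities.  See the package vignette.
# Inputs (fix via environment): APC=ON, TGFB_e=ON, IL2_e=ON, all other
#                               *_e cytokine inputs OFF.
TCR* = APC
CD28* = APC
CTLA4* = FOXP3 and TCR
NFAT* = TCR and CD28
NFKB* = TCR and CD28
IRF4* = NFAT
TGFBR* = TGFB_e or TGFB
SMAD3* = TGFBR
TGFB* = FOXP3
IL12R* = IL12_e
STAT4* = IL12R and not GATA3
IL6* = IL6_e
IL6R* = IL6 or IL6_e
GP130* = IL6R
IL27R* = IL27_e
IL2* = NFAT and not FOXP3
IL2R_1* = IL2 or IL2_e
IL2R_2* = IL2R_1 and IL2
IL2RA* = IL2R_1 and STAT5_1
IL2RB* = IL2R_1
STAT5_1* = IL2R_1
STAT5_2* = IL2R_2
IFNG* = (TBET or STAT4) and not GATA3
IFNGR* = (IFNG or IFNG_e) and not SOCS1
STAT1* = IFNGR or IL27R
TBET* = (TBET or STAT1) and not GATA3
SOCS1* = TBET or STAT1
RUNX3* = TBET and not GATA3
IL4* = GATA3 and not STAT1
IL4R_1* = (IL4 or IL4_e) and not SOCS1
IL4R_2* = IL4R_1 and IL4
STAT6* = IL4R_1 or IL4R_2
GATA3* = (GATA3 or STAT6) and not TBET
STAT3* = IL10R or IL21R or (IL23R and RORGT) or GP130
IL10* = STAT3
IL10R* = IL10 or IL10_e
IL21* = STAT3 and NFAT
IL21R* = IL21 or IL21_e
IL23* = APC and NFKB
IL23R* = (IL23 or IL23_e) and STAT3
RORGT* = (SMAD3 and STAT3) and not (GATA3 or TBET or FOXP3)
FOXP3* = (SMAD3 and STAT5_1) and not (GATA3 or TBET or RORGT)
IL17* = RORGT and STAT3
IL17F* = RORGT and STAT3
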