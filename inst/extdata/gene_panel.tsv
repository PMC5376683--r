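gene	group
ACTA2	fibroblast
COL1A1	fibroblast
TNC	fibroblast
FN1	fibroblast
FAP	fibroblast
FSP1	fibroblast
MMP2	fibroblast
LOX	fibroblast
LOXL2	fibroblast
VIM	fibroblast
CD44	fibroblast
CAV1	fibroblast
CDH1	epithelial
EPCAM	epithelial
CXCL12	chemokine_soluble
PDGFA	chemokine_soluble
VEGFA	chemokine_soluble
HGF	chemokine_soluble
CCL5	chemokine_soluble
IL6	chemokine_soluble
CTGF	chemokine_soluble
FOXF1	transcription_factor
GLI1	transcription_factor
HEY1	transcription_factor
RUNX2	transcription_factor
STAT3	transcription_factor
CCNA2	proliferation
MKI67	proliferation
CDKN1A	proliferation
ALDH1A3	bcsc
ALDH1A1	bcsc
ITGA6	bcsc
PROM1	bcsc
POU5F1	pluripotency
SOX2	pluripotency
NANOG	pluripotency
KLF4	pluripotency
LIN28A	pluripotency
SNAI1	emt
SNAI2	emt
TWIST1	emt
ZEB1	emt
GAPDH	reference
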