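gene	polarity
CDH1	epithelial
DSP	epithelial
EPCAM	epithelial
CLDN1	epithelial
CLDN3	epithelial
CLDN4	epithelial
CLDN7	epithelial
OCLN	epithelial
TJP1	epithelial
TJP3	epithelial
CRB3	epithelial
ESRP1	epithelial
ESRP2	epithelial
GRHL2	epithelial
KRT5	epithelial
KRT7	epithelial
KRT8	epithelial
KRT14	epithelial
KRT18	epithelial
KRT19	epithelial
MUC1	epithelial
RAB25	epithelial
ST14	epithelial
SPINT1	epithelial
SPINT2	epithelial
F11R	epithelial
DSG2	epithelial
DSG3	epithelial
PKP3	epithelial
JUP	epithelial
VIM	mesenchymal
CDH2	mesenchymal
FN1	mesenchymal
ZEB1	mesenchymal
ZEB2	mesenchymal
SNAI1	mesenchymal
SNAI2	mesenchymal
TWIST1	mesenchymal
TWIST2	mesenchymal
FOXC1	mesenchymal
FOXC2	mesenchymal
PRRX1	mesenchymal
MMP2	mesenchymal
MMP3	mesenchymal
MMP9	mesenchymal
MMP14	mesenchymal
ACTA2	mesenchymal
TAGLN	mesenchymal
SPARC	mesenchymal
COL1A1	mesenchymal
COL1A2	mesenchymal
COL3A1	mesenchymal
COL5A1	mesenchymal
COL5A2	mesenchymal
COL6A3	mesenchymal
THBS1	mesenchymal
THBS2	mesenchymal
POSTN	mesenchymal
FBN1	mesenchymal
FAP	mesenchymal
PDGFRA	mesenchymal
PDGFRB	mesenchymal
S100A4	mesenchymal
ITGB1	mesenchymal
ITGA5	mesenchymal
VCAN	mesenchymal
LUM	mesenchymal
DCN	mesenchymal
BGN	mesenchymal
EMP3	mesenchymal
SERPINE1	mesenchymal
TNC	mesenchymal
WNT5A	mesenchymal
TGFB1	mesenchymal
TGFBI	mesenchymal
CALD1	mesenchymal
CNN1	mesenchymal
FSTL1	mesenchymal
GREM1	mesenchymal
INHBA	mesenchymal
AXL	mesenchymal
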