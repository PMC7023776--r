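gene	klass
CDH1	epithelial
EPCAM	epithelial
GRHL2	epithelial
CTNNB1	epithelial
CTNNA1	epithelial
COL4A2	epithelial
COL8A2	epithelial
VCAM1	epithelial
MMP9	epithelial
DSP	epithelial
OCLN	epithelial
CLDN4	epithelial
CLDN7	epithelial
KRT18	epithelial
KRT19	epithelial
ESRP1	epithelial
VIM	mesenchymal
CDH2	mesenchymal
ZEB1	mesenchymal
ZEB2	mesenchymal
FN1	mesenchymal
PPM1F	mesenchymal
LOX	mesenchymal
MSN	mesenchymal
WNT5A	mesenchymal
SPARC	mesenchymal
COL5A2	mesenchymal
COL3A1	mesenchymal
COL1A2	mesenchymal
AXL	mesenchymal
SNAI1	mesenchymal
SNAI2	mesenchymal
TWIST1	mesenchymal
TWIST2	mesenchymal
FOXC2	mesenchymal
MMP2	mesenchymal
MMP3	mesenchymal
ITGA5	mesenchymal
FBN1	mesenchymal
TNC	mesenchymal
POSTN	mesenchymal
THBS1	mesenchymal
SERPINE1	mesenchymal
TGFB1	mesenchymal
TGFB2	mesenchymal
GSC	mesenchymal
CDH11	mesenchymal
PDGFRB	mesenchymal
S100A4	mesenchymal
FSTL1	mesenchymal
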