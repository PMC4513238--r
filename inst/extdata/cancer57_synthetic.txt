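# 57-gene cancer-predisposition panel: the 23 cancer genes of the ACMG-56
# secondary-findings list plus 34 representative genes from clinical cancer
# NGS panels.  The 34-gene complement is a synthetic stand-in for a
# non-deposited panel definition.
BRCA1
BRCA2
TP53
STK11
MLH1
MSH2
MSH6
PMS2
APC
MUTYH
VHL
MEN1
RET
PTEN
RB1
SDHD
SDHAF2
SDHC
SDHB
TSC1
TSC2
WT1
NF2
ATM
ATR
BRIP1
PALB2
BARD1
CHEK2
CDH1
CDK4
CDKN2A
BMPR1A
SMAD4
EPCAM
PRSS1
BLM
NBN
RAD50
RAD51C
RAD51D
XPC
FANCA
FANCC
FH
FLCN
GREM1
HOXB13
KIT
MET
MRE11A
PTCH1
SUFU
TERT
AXIN2
POLD1
POLE
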