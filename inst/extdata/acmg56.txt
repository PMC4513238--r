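# ACMG SF v1.0: the 56 genes recommended for reporting of secondary findings.
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
COL3A1
FBN1
TGFBR1
TGFBR2
SMAD3
ACTA2
MYH11
MYBPC3
MYH7
TNNT2
TNNI3
TPM1
MYL3
ACTC1
PRKAG2
GLA
MYL2
LMNA
RYR2
PKP2
DSP
DSC2
DSG2
TMEM43
SCN5A
KCNQ1
KCNH2
KCNE1
KCNE2
LDLR
APOB
PCSK9
RYR1
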