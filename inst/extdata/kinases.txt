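# Human protein-kinase gene symbols used to annotate structural-screen hits
# and as the kinase universe for K-control sampling on real data.
AKT1
AKT2
AKT3
ATM
ATR
AURKA
AURKB
BRAF
BTK
CDK1
CDK2
CDK4
CDK5
CDK6
CDK7
CDK9
CHEK1
CHEK2
CSNK2A1
EGFR
ERBB2
ERBB4
FGFR1
FGFR2
FYN
GSK3B
IGF1R
INSR
JAK1
JAK2
JAK3
KDR
KIT
LCK
LYN
MAP2K1
MAP2K2
MAP2K6
MAP3K5
MAPK1
MAPK14
MAPK3
MAPK8
MAPKAPK2
MET
MTOR
PDGFRB
PIM1
PLK1
PRKACA
PRKCA
RAF1
ROCK1
RPS6KA1
RPS6KB1
SGK1
SRC
STK11
SYK
TTK
WEE1
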