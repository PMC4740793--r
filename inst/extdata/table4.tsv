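gene	n_subnetworks_critical
TP53	20
AKT1	20
PCNA	17
SRC	15
INS-IGF2	12
SF3A2	10
BIRC5	10
DKC1	9
ESR1	8
BUB1	7
BRCA1	7
RPL11	7
YBX1	7
RPS16	6
GRB2	6
POLR2H	6
HNRNPK	5
MDM2	5
CASP3	5
POLR2A	5
CDK5	5
SP1	5
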