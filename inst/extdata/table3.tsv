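root	z
AKT1	2.777
IL12B	2.585
EGFR	2.521
MAPK14	2.265
TIAM1	2.073
SGK1	1.498
RFC1	1.434
SEMA7A	1.306
NOS3	1.115
VAV1	1.051
PLA2G4A	0.923
CLPP	0.859
MMAA	0.795
CDK7	0.667
LIPF	0.411
MAP2K2	0.220
PREP	0.156
FAP	-0.164
PDK2	-0.867
PRKAB1	-1.442
BPHL	-1.570
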