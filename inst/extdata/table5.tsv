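gene	control_pct	experimental_pct	z_gt_1_pct	z_gt_2_pct
SF3A2	37.5	47.6	60.0	100.0
ESR1	25.0	38.1	50.0	80.0
BIRC5	37.5	47.6	70.0	80.0
MDM2	6.3	23.8	30.0	60.0
STAT1	0.0	14.3	30.0	60.0
POLR2H	18.8	28.6	50.0	60.0
CTNNB1	6.3	9.5	20.0	40.0
CREBBP	0.0	14.3	30.0	40.0
RAC1	0.0	14.3	30.0	40.0
JUN	6.3	19.0	40.0	40.0
FOS	6.3	14.3	20.0	40.0
STAT3	6.3	19.0	20.0	40.0
IL8	0.0	9.5	20.0	40.0
NFKBIA	0.0	9.5	20.0	40.0
BRCA1	50.0	33.3	40.0	20.0
HDAC1	37.5	14.3	10.0	0.0
CDK5	0.0	23.8	30.0	0.0
SDC2	18.8	19.0	30.0	0.0
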