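gene	percent_control
SGK1	59
EGFR	60
CDK7	79
MAP2K2	80
MAPK14	88
AKT1	100
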