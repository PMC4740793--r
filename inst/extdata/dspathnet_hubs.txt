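# Hub genes (connectivity > 14) of an independently derived drug-specific
# signaling pathway network, used for cross-validation of critical nodes.
BRCA1
TP53
ESR1
STAT1
JUN
SP1
AKT1
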