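cohort	mean	sd	n
L_control	117.3	12.9	20
R_control	117.6	15.6	16
K_control	133.7	13.3	19
experimental	131.4	18.8	21
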