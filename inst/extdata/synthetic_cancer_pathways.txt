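# Curated stand-in list of cancer-related KEGG pathway names (cancer-type
# pathways plus pathways involved in cancer development or maintenance).
Melanoma
Small cell lung cancer
Non-small cell lung cancer
Chronic myeloid leukemia
Pancreatic cancer
Glioma
Prostate cancer
Bladder cancer
Pathways in cancer
Apoptosis
Cell cycle
VEGF signaling pathway
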