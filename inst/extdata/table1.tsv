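pdb_code	gene	smap_p	vina_score	is_template	is_template_homolog	is_kinase
1Z0M	PRKAB1	NA	-4.7	TRUE	FALSE	FALSE
1Z68	FAP	1.0e-10	-5.0	FALSE	TRUE	FALSE
3A8N	TIAM1	9.22e-04	-4.8	FALSE	FALSE	FALSE
1SXJ	RFC1	4.79e-03	-5.1	FALSE	FALSE	FALSE
3B2V	EGFR	6.79e-03	-5.1	FALSE	FALSE	TRUE
1S9I	MAP2K2	6.92e-03	-5.1	FALSE	FALSE	TRUE
2BU7	PDK2	9.85e-03	-4.9	FALSE	FALSE	FALSE
3DDU	PREP	1.05e-02	-4.5	FALSE	FALSE	FALSE
3NVQ	SEMA7A	1.63e-02	-4.6	FALSE	FALSE	FALSE
1F45	IL12B	1.71e-02	-5.7	FALSE	FALSE	FALSE
1CJY	PLA2G4A	1.85e-02	-4.7	FALSE	FALSE	FALSE
2ONL	MAPK14	1.96e-02	-5.7	FALSE	FALSE	TRUE
3O96	AKT1	2.49e-02	-5.5	FALSE	FALSE	TRUE
1K8Q	LIPF	2.81e-02	-4.5	FALSE	FALSE	FALSE
3KY9	VAV1	3.01e-02	-6.4	FALSE	FALSE	FALSE
1UA2	CDK7	3.21e-02	-5.5	FALSE	FALSE	TRUE
3HDN	SGK1	3.37e-02	-4.1	FALSE	FALSE	TRUE
2OCI	BPHL	3.50e-02	-5.4	FALSE	FALSE	FALSE
2WWW	MMAA	3.71e-02	-4.6	FALSE	FALSE	FALSE
3EAH	NOS3	3.77e-02	-5.7	FALSE	FALSE	FALSE
1TG6	CLPP	4.05e-02	-2.6	FALSE	FALSE	FALSE
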