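genome	recall_before	mean_error_before	recall_after	mean_error_after
E_coli_K12	80.62	18.67	86.79	13.50
E_coli_O157_Sakai	76.83	17.97	84.62	14.31
S_enterica_Typhi_CT18	67.32	27.31	77.27	21.92
S_enterica_Paratypi_ATCC9150	78.34	20.38	83.73	16.05
C_pneumoniae_CWL029	74.52	19.17	80.66	16.10
S_agalactiae_2603	74.73	20.69	78.30	14.27
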