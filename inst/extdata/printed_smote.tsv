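genome	recall_before	mean_error_before	recall_after	mean_error_after
E_coli_K12	86.79	13.50	92.35	7.26
E_coli_O157_Sakai	84.62	14.31	89.85	9.64
S_enterica_Typhi_CT18	77.27	21.92	86.17	11.36
S_enterica_Paratypi_ATCC9150	83.73	16.05	91.60	7.64
C_pneumoniae_CWL029	80.66	16.10	83.51	13.70
S_agalactiae_2603	78.30	14.27	87.09	10.42
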