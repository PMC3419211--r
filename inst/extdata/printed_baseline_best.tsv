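genome	recall_before	mean_error_before	recall_after	mean_error_after
E_coli_K12	93.11	51.24	92.35	7.26
E_coli_O157_Sakai	89.12	33.50	89.85	9.64
S_enterica_Typhi_CT18	80.22	25.39	86.17	11.36
S_enterica_Paratypi_ATCC9150	90.78	43.26	91.60	7.64
C_pneumoniae_CWL029	79.71	28.89	83.51	13.70
S_agalactiae_2603	80.76	35.67	87.09	10.42
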