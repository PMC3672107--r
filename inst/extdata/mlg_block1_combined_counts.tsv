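mlg	n_control	freq_control	n_case	freq_case
MLG00002000	18	0.006	13	0.005
MLG00011001	134	0.047	154	0.053
MLG00020002	354	0.124	349	0.121
MLG00101000	42	0.015	43	0.015
MLG00110001	228	0.080	215	0.075
MLG00110002	9	0.003	6	0.002
MLG00200000	40	0.014	37	0.013
MLG01010001	15	0.005	20	0.007
MLG01011011	9	0.003	4	0.001
MLG01020012	34	0.012	36	0.013
MLG01110011	8	0.003	9	0.003
MLG10020111	22	0.008	9	0.003
MLG11001110	137	0.048	158	0.055
MLG11010002	11	0.004	17	0.006
MLG11010012	12	0.004	8	0.003
MLG11010111	716	0.251	731	0.254
MLG11011110	24	0.008	16	0.006
MLG11020111	74	0.026	96	0.033
MLG11020112	8	0.003	9	0.003
MLG11100110	245	0.086	213	0.074
MLG11100111	7	0.002	5	0.002
MLG11110110	31	0.011	24	0.008
MLG12000210	7	0.002	11	0.004
MLG12010121	25	0.009	33	0.011
MLG21010220	13	0.005	21	0.007
MLG22000111	12	0.004	16	0.006
MLG22000121	7	0.002	18	0.006
MLG22000220	394	0.138	421	0.146
MLG22010220	99	0.035	87	0.030
MLG22010221	8	0.003	5	0.002
MLG-rare	113	0.040	96	0.033
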