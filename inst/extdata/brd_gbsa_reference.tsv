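system	inhibitor	dEele	dEele_sd	dEvdw	dEvdw_sd	dGgb	dGgb_sd	dGsurf	dGsurf_sd	neg_TdS	neg_TdS_sd	dGpol_printed	dGbind_printed	dGexp
BRD4	H1B	-29.97	9.39	-41.78	3.38	42.71	7.61	-5.70	0.44	18.65	5.52	12.74	-16.09	NA
BRD4	JQ1	-22.91	15.93	-28.51	7.13	33.53	15.38	-3.50	0.90	15.01	6.13	10.62	-6.38	-10.00
BRD4	TVU	-34.45	9.84	-44.36	2.92	48.59	7.69	-5.97	0.33	19.34	6.15	14.14	-16.85	NA
BRD9	H1B	-43.82	7.69	-48.74	2.89	52.35	6.15	-6.29	0.30	25.11	4.35	3.62	-21.38	-10.16
BRD9	JQ1	15.43	9.03	-40.37	4.25	-2.66	8.85	-4.58	0.41	20.24	3.75	12.77	-11.94	NA
BRD9	TVU	-39.46	4.91	-50.03	3.28	50.06	4.22	-6.33	0.29	22.58	4.15	10.60	-23.17	-11.35
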