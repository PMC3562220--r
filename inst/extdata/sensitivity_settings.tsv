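label	n_features	median_pid	s30_printed	s100_printed
12, 0.5	1454	33.12	460.4	-1858
3,0.3	2350	39.75	1157.5	-1625
3,0.5	1940	34.72	898.4	-1532
3,0.8	1653	30.60	735	-1407
3,0.3 u 3,0.5	2363	36.16	1278.2	-1253
3,0.3 u 3,0.8	2384	35.69	1313.3	-1185
3,0.5 u 3,0.8	2022	32.22	1055.4	-1200
3,0.3 u 12,0.5	2310	36.59	1214.4	-1342
3,0.5 u 12,0.5	2037	33.40	1035	-1303
3,0.8 u 12,0.5	1816	30.37	904.9	-1221
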