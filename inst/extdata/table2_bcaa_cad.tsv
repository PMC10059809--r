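snp	gene	chr	effect_allele	other_allele	eaf	beta_exp	se_exp	pval_exp	or_out	ci_low	ci_high	pval_out
rs116564150	PPM1K	4	A	G	0.013	0.31	0.05	5.79e-12	1.07	0.97	1.18	0.188
rs145585828	PPM1K	4	A	C	0.016	-0.25	0.04	2.06e-9	1.01	0.93	1.11	0.753
rs141413744	PPM1K	4	C	T	0.037	-0.20	0.03	1.24e-14	1.02	0.95	1.11	0.555
rs1808860	PPM1K	4	C	T	0.436	0.11	0.01	1.95e-31	1.01	0.99	1.03	0.458
rs34752329	PPM1K	4	A	G	0.369	0.11	0.01	5.69e-30	1.01	0.99	1.03	0.286
rs6838172	PPM1K	4	A	G	0.320	0.11	0.01	5.68e-27	1.01	0.99	1.03	0.348
rs7680307	PPM1K	4	C	T	0.259	0.11	0.01	5.87e-20	1.01	0.99	1.04	0.421
rs9637599	PPM1K	4	C	A	0.470	0.11	0.01	7.64e-36	1.00	0.98	1.02	0.757
rs13125860	PPM1K	4	A	T	0.389	-0.10	0.01	1.69e-25	1.00	0.98	1.02	0.904
rs17732955	PPM1K	4	T	C	0.295	0.10	0.01	1.09e-22	1.02	1.00	1.04	0.116
rs1808859	PPM1K	4	C	T	0.391	0.10	0.01	5.92e-26	1.00	0.98	1.02	0.696
rs58101275	TRMT61A	14	G	A	0.790	0.09	0.02	9.87e-10	1.01	0.99	1.04	0.222
rs893970	PPM1K	4	C	T	0.447	0.09	0.01	2.98e-19	1.00	0.98	1.02	0.689
rs13030345	MRPL33	2	T	G	0.191	0.07	0.01	4.52e-9	1.01	0.98	1.03	0.488
rs1420601	CBLN1	16	C	T	0.400	0.07	0.01	3.63e-8	1.01	0.99	1.03	0.244
rs1919128	C2orf16	2	G	A	0.275	0.07	0.01	1.18e-10	1.01	0.99	1.03	0.422
rs7656569	PPM1K	4	A	C	0.202	0.07	0.01	6.74e-9	1.01	0.98	1.04	0.464
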