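snp_id	chrom	pos	gene	p_I	p_II	p_III	p_current
X_114995979	X	114995979	ADGRG2	0.99	0.62	0.45	0.39
10_28703125	10	28703125	AVEN	0.02	0.30	0.51	0.59
X_116153810	X	116153810	DMD	0.05	0.46	0.53	0.58
3_98450919	3	98450919	SPATA6	0.08	0.53	0.57	0.59
2_100376419	2	100376419	ERBB4	0.08	0.29	0.47	0.56
23_27215001	23	27215001	SKIV2L	0.37	0.58	0.78	0.84
1_88050696	1	88050696	USP13	0.22	0.57	0.63	0.64
1_16724678	1	16724678	IL1R2	0.68	0.33	0.29	0.26
13_76932968	13	76932968	SULF2	0.19	0.38	0.51	0.61
26_17465791	26	17465791	BLNK	0.41	0.74	0.79	0.83
19_24812617	19	24812617	SPATA22	0.80	0.49	0.42	0.39
23_25552635	23	25552635	BOLA-DRB2	0.22	0.49	0.60	0.62
1_65433706	1	65433706	GSK3B	0.54	0.21	0.17	0.16
12_35934370	12	35934370	LATS2	0.42	0.23	0.14	0.08
9_90155533	9	90155533	ESR1	0.45	0.24	0.16	0.13
20_32030332	20	32030332	GHR	0.42	0.61	0.70	0.73
11_28602889	11	28602889	EPAS1	0.41	0.60	0.64	0.71
19_5258770	19	5258770	SPATA16	0.92	0.65	0.69	0.62
11_31296603	11	31296603	FSHR	0.03	0.23	0.25	0.26
20_39017985	20	39017985	PRLR	0.70	0.61	0.50	0.49
14_1801116	14	1801116	DGAT1	0.93	0.71	0.82	0.77
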