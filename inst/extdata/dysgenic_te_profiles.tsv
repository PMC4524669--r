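te	abund_log2	pirna_log2	expr_d	expr_nd	ppd_d	ppd_nd	te_type
Helena	1.71	8.64	18.25	0.83	0.31	53.04	I
495	0.21	2.35	1.05	0.33	37.79	119.30	I
967	0.17	5.75	2.28	0.53	0.21	6.72	I
Penelope	4.95	5.30	61.48	25.42	11.19	32.06	I
Slicemaster	3.88	8.89	1.69	0.18	12.63	13.89	II
Skippy	1.64	2.50	321.77	2.65	74.92	47.03	III
Paris	1.67	5.50	18.94	9.36	12.22	6.25	III
Nausicaa	-0.06	2.24	86.90	4.43	14.19	44.83	IV
656	-0.01	7.25	3.20	1.07	0.34	13.46	IV
1012	-0.06	4.27	3.01	0.42	0.27	52.99	IV
190	-0.12	3.53	1.32	0.44	16.66	45.73	IV
620	-0.22	3.11	2.35	0.45	0.00	9.93	IV
938	-0.34	1.87	10.42	0.63	0.00	0.00	V
750	-0.30	0.03	28.03	1.54	7.17	12.84	VI
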