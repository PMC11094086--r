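position	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
1	0.25	0.12	-0.02	0.24	0.6	0.27	-0.28	0.04	-0.17	-0.21	0.1	0.07	0.02	-0.09	0.25	0.05	0.14	-0.06	0.06	0.8
2	0.26	-0.03	0.04	-0.03	-0.18	0.23	0.15	1.5	-0.01	3	2.5	0.08	-0.3	0.07	0.28	0.19	0.19	0.11	-0.18	-0.05
3	-0.13	0.13	0.5	0.2	0.24	0.08	0.11	-0.19	-0.18	0.09	-0.17	-0.17	0.07	0.2	-0.16	-0.23	-0.2	0.17	0.02	-0.01
4	0.2	0.26	-0.22	0.14	0.07	0.28	-0.2	-0.14	0.13	0.17	0.26	-0.17	0.2	-0.09	0.13	0.16	0.27	-0.19	-0.19	-0.04
5	0.09	-0.15	0.29	0.19	-0.07	0.07	-0.14	0.2	-0.3	0.04	0.26	-0.07	0.15	-0.05	0.24	0.07	-0.12	-0.28	-0.03	-0.22
6	0.01	-0.02	0.27	-0.07	-0.04	-0.1	0.01	0.12	-0.07	-0.16	0.14	0.27	-0.03	0.04	0.06	-0.21	-0.21	-0.22	-0.11	0.19
7	0.14	0.26	-0.25	0.11	-0.28	-0.09	0.11	-0.16	0.01	-0.25	-0.1	0.28	0.02	0.05	0.08	-0.25	0.13	0.11	-0.23	0.06
8	-0.22	0.29	0.01	-0.3	0.28	-0.06	0.29	-0.27	-0.3	-0.25	0.01	0.14	0.02	0.13	0.26	-0.02	-0.11	0.26	-0.19	0.18
9	0.09	-0.23	-0.07	0.2	-0.04	0.17	0.16	2	0.05	2.5	0.15	0.14	-0.3	-0.06	0.21	0.17	0.17	3	0.14	0.16
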