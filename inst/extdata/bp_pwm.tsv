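position	A	C	G	T
1	0.15	0.30	0.10	0.45
2	0.05	0.10	0.05	0.80
3	0.35	0.20	0.15	0.30
4	0.94	0.02	0.02	0.02
5	0.10	0.40	0.05	0.45
6	0.25	0.25	0.25	0.25
7	0.25	0.25	0.25	0.25
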