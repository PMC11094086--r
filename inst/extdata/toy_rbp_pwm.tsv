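position	A	C	G	T
1	0.05	0.05	0.05	0.85
2	0.05	0.05	0.85	0.05
3	0.05	0.85	0.05	0.05
4	0.85	0.05	0.05	0.05
5	0.05	0.05	0.05	0.85
6	0.05	0.05	0.85	0.05
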