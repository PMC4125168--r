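null	alt	stat	df	p
B	A	149.8160	1	1.90e-34
A	C	66.6663	1	3.22e-16
D	C	3.9049	1	0.04815
C	G	15.2620	11	0.1708
A	E	71.2014	1	3.22e-17
F	E	6.0161	1	0.01418
E	G	10.7269	11	0.4664
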