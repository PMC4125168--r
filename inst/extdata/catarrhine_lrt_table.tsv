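null	alt	stat	df	p
B	A	332.818	1	2.34e-74
A	C	20.0427	1	7.57e-6
D	C	1.1689	1	0.2796
C	L	25.9617	21	0.2079
A	E	28.0456	1	1.18e-7
F	E	0.7165	1	0.3973
E	L	17.9588	21	0.6516
A	G	12.6522	1	3.75e-4
H	G	15.4436	1	8.50e-5
G	L	33.3522	21	0.04245
A	I	21.8502	1	2.95e-6
J	I	15.8447	1	6.88e-5
I	L	24.1542	21	0.2856
J	L	39.9989	22	0.01081
A	K	30.1641	2	2.82e-7
E	K	2.1185	1	0.1455
K	L	15.8403	20	0.7265
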