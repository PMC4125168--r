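model	description	omega0	omega1	omega2	lnL	np
A	one-ratio	0.18967	NA	NA	-4803.2004	25
B	one-ratio, omega0 fixed at 1	1	NA	NA	-4969.6092	24
C	two-ratio: human and orangutan branches	0.16649	0.70206	NA	-4793.1791	26
D	two-ratio: human and orangutan branches, omega1 fixed at 1	0.16660	1	NA	-4793.7635	25
E	two-ratio: human, gorilla and orangutan branches	0.15984	0.77453	NA	-4789.1776	26
F	two-ratio: human, gorilla and orangutan branches, omega1 fixed at 1	0.15994	1	NA	-4789.5358	25
G	two-ratio: great ape branches plus their stem	0.16431	0.39834	NA	-4796.8743	26
H	two-ratio: great ape branches plus their stem, omega1 fixed at 1	0.16451	1	NA	-4804.5961	25
I	two-ratio: human, gorilla, orangutan and cercopithecine branches plus cercopithecine stem	0.15182	0.43710	NA	-4792.2753	26
J	same branch set as I, omega1 fixed at 1	0.15199	1	NA	-4800.1977	25
K	three-ratio: human/gorilla/orangutan (omega1), cercopithecines plus stem (omega2)	0.15194	0.77665	0.24051	-4788.1184	27
L	free-ratio	NA	NA	NA	-4780.1982	47
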