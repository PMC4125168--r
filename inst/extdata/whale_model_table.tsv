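model	description	omega0	omega1	omega2	lnL	np
A	one-ratio	0.31510	NA	NA	-5047.2740	15
B	one-ratio, omega0 fixed at 1	1	NA	NA	-5122.1820	14
C	two-ratio: toothed-whale branches plus stem and baleen-whale branches plus stem	0.15926	0.74234	NA	-5013.9409	16
D	same branch set as C, omega1 fixed at 1	0.15938	1	NA	-5015.8933	15
E	two-ratio: all whale branches plus whale stem	0.12471	0.69721	NA	-5011.6733	16
F	same branch set as E, omega1 fixed at 1	0.12110	1	NA	-5014.6813	15
G	free-ratio	NA	NA	NA	-5006.3099	27
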