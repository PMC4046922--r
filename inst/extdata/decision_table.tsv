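label	snp_conditions	motif_conditions	priority
H	7028C	.	1
L3	7028T;10873C;10400C	16223T	1
N*	7028T;12705T	.	1
K	12308G;10550G	16224C;16311C	2
U*	12308G;10550A	.	2
HV	7028T;12308A;12705C	.	3
R0	7028T;12308A;12705C;14766T	16293C	4
HV0	7028T;12308A;12705C	16298C	4
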