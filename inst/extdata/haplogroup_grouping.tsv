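raw_label	category
AS	AS
H	H
AF	AF
K	K
U5	U5
HV0	HV0
HV	HV
J	J
T	T
N*	N*
N1	N1
U7	U7
U3	U3
U1	U1
U6	U6
R0	R0
U4	U4
U2	U2
R+	R+
X	X
U+	U+
W	W
U*	U*
I	I
N2	N2
L0	AF
L1	AF
L2	AF
L3	AF
L4	AF
L5	AF
L6	AF
L7	AF
M1	AF
A	AS
B	AS
C	AS
D	AS
E	AS
F	AS
G	AS
M*	AS
M3-48	AS
N9	AS
R5	AS
R9	AS
Q	AS
Y	AS
Z	AS
U8	U+
U9	U+
R1	R+
R2	R+
pre-V	HV0
V	HV0
HV0b	HV0
HV0c	HV0
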