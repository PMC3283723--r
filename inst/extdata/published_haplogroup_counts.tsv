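# Published haplogroup counts for the two study populations (149 Barghuts,
# 98 Altaian Kazakhs); input fixture for frequencyTable()/componentShares().
haplogroup	Barghuts	Altaian_Kazakhs
A4	8	3
A8	1	0
B4	9	1
B5	3	3
C4	24	8
C5	5	0
C6	1	0
D2	3	0
D3	2	0
D4	47	22
D5	1	4
F1	4	5
F2	1	0
G2	13	1
G3	1	1
M13	2	0
M7	3	5
M9a	1	1
N9a	2	2
R9c1	1	0
Y1	1	1
Z	4	2
H	3	13
J	0	5
HV	2	3
U2	1	1
U3	0	1
U4	0	4
U5	1	2
U7	1	0
U8	2	0
K	2	2
T	0	2
T1	0	2
R2	0	1
I	0	3
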