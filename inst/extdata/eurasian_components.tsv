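# Eastern vs western Eurasian assignment of the haplogroups in the published-count
# fixture, following the conventional macrohaplogroup geography.
haplogroup	component
A4	eastern
A8	eastern
B4	eastern
B5	eastern
C4	eastern
C5	eastern
C6	eastern
D2	eastern
D3	eastern
D4	eastern
D5	eastern
F1	eastern
F2	eastern
G2	eastern
G3	eastern
M13	eastern
M7	eastern
M9a	eastern
N9a	eastern
R9c1	eastern
Y1	eastern
Z	eastern
H	western
J	western
HV	western
U2	western
U3	western
U4	western
U5	western
U7	western
U8	western
K	western
T	western
T1	western
R2	western
I	western
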