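# Illustrative haplogroup tree fixture. Node motifs encode only the partial
# diagnostic mutations given in the accompanying text for the clades of
# interest (plus a minimal macrohaplogroup scaffold); it is not a PhyloTree
# replacement. Tokens use the canonical dialect of parseVariant().
node	parent	mutations
mt-MRCA
N	mt-MRCA
R	N
R11'B6	R	16189 12950
R11	R11'B6
R11b	R11
R11b1	R11b	16390 8278.1C
B4'B5	R	16189 8281-8289d
B4	B4'B5	16217
B4b	B4
B4b1	B4b
B4b1a	B4b1
B4b1a3	B4b1a	146 16086
B4b1a3a	B4b1a3	408A 9055 9388T 9615
B4c	B4
B4c1	B4c	3497 16311
B4c1a	B4c1
B4c1a2	B4c1a	16527 16311!
B4d1	B4	15038
B4j	B4	16223 16362
B5	B4'B5	8584
B5b	B5
B5b2b	B5b	207 15758
R9	R
R9c	R9
R9c1	R9c
R9c1a	R9c1
R9c1a1	R9c1a	16157
F2	R9
F2e	F2	16260
N9	N
N9a	N9	16257A 16261
N9a3	N9a
N9a3a	N9a3	4913 12636
N9a8	N9a	11368 15090
M	mt-MRCA	489 10400
M9	M
M9a	M9	16234
M9a4	M9a
M9a4b	M9a4	6815
M10	M
M10a	M10
M10a1	M10a	16129
M10a1a2a	M10a1	10529 16129!
M10a2	M10a
M10a2a	M10a2
M11	M
M11b	M11
M11b1	M11b	146 10685 14790
M11b2	M11b	459.1C 5192
M11d	M11
M13	M
M13a	M13
M13a1	M13a
M13a1b	M13a1	5045
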