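# Synthetic mitochondrial annotation: canonical human mtDNA gene order and
# coordinates (1-based, rCRS-like frame); tRNA clusters are approximated as
# blocks filling the gaps between named features. Types: rRNA, tRNA, protein.
# ND6 is the single light-strand protein gene.
feature	type	start	end	strand
RNR1	rRNA	648	1601	+
RNR2	rRNA	1671	3229	+
TRN_F	tRNA	577	647	+
TRN_V	tRNA	1602	1670	+
TRN_L1	tRNA	3230	3306	+
ND1	protein	3307	4262	+
TRN_IQM	tRNA	4263	4469	+
ND2	protein	4470	5511	+
TRN_WANCY	tRNA	5512	5903	+
CO1	protein	5904	7445	+
TRN_SD	tRNA	7446	7585	+
CO2	protein	7586	8269	+
TRN_K	tRNA	8295	8364	+
ATP8	protein	8366	8572	+
ATP6	protein	8527	9207	+
CO3	protein	9207	9990	+
TRN_G	tRNA	9991	10058	+
ND3	protein	10059	10404	+
TRN_R	tRNA	10405	10469	+
ND4L	protein	10470	10766	+
ND4	protein	10760	12137	+
TRN_HSL	tRNA	12138	12336	+
ND5	protein	12337	14148	+
ND6	protein	14149	14673	-
TRN_E	tRNA	14674	14746	+
CYB	protein	14747	15887	+
TRN_T	tRNA	15888	15953	+
TRN_P	tRNA	15956	16023	+
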