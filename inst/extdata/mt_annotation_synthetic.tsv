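region	start	end	type	strand
control	1	576	control	+
tRNA-F	577	647	rna	+
rRNA-12S	648	1601	rna	+
tRNA-V	1602	1670	rna	+
rRNA-16S	1671	3229	rna	+
tRNA-L1	3230	3306	rna	+
ND1	3307	4262	coding	+
tRNA-block1	4263	4469	rna	+
ND2	4470	5511	coding	+
tRNA-block2	5512	5903	rna	+
CO1	5904	7445	coding	+
tRNA-block3	7446	7585	rna	+
CO2	7586	8269	coding	+
tRNA-K	8270	8365	rna	+
ATP8	8366	8526	coding	+
ATP6	8527	9206	coding	+
CO3	9207	9990	coding	+
tRNA-G	9991	10058	rna	+
ND3	10059	10404	coding	+
tRNA-R	10405	10469	rna	+
ND4L	10470	10759	coding	+
ND4	10760	12137	coding	+
tRNA-block4	12138	12336	rna	+
ND5	12337	14148	coding	+
ND6	14149	14673	coding	-
tRNA-E	14674	14746	rna	+
CYB	14747	15887	coding	+
tRNA-TP	15888	16023	rna	+
control-HVS1	16024	16569	control	+
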