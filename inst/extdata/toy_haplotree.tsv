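mt-MRCA	-	-
N	mt-MRCA	8701 9540 10398 10873 15301
R	N	12705 16223
R0	R	73
HV	R0	14766
H	HV	2706 7028
H1	H	3010
H13	H	4745 13762
H13a	H13	14872
H13a2	H13a	4639
HV2	HV	152 16217
V	HV	4580
R2'JT	R	4216
JT	R2'JT	11251
J	JT	295 10398! 16069
T	JT	709 16294
R2	R2'JT	13500 16071
R2a	R2	2442 10044
U	R	11467 12308 12372
U1	U	11009 12879
U1a	U1	13104 14070
U3	U	13743 16343
U5	U	3197 9477 16270
U5a	U5	14793
U7	U	8137 16309T
K	U	1189 10550 14798
N1	N	10238 16145
N1a	N1	669 2702
I	N1	10034 16129 15301!
N2	N	13780
W	N2	204 1243
N3	N	15946
X	N	6221 6371
M	mt-MRCA	489 10400 14783 15043
M5	M	1888 12477
C	M	3552A 9545 11914
D	M	4883 5178A
L2	mt-MRCA	2416 8206 9221
L3	mt-MRCA	769 1018
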