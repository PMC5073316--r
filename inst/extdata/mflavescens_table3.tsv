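codon	aa	count	rscu_printed
UUU	F	370	1.88
UUC	F	23	0.12
UUA	L2	459	5.1
UUG	L2	25	0.28
CUU	L1	33	0.37
CUC	L1	0	0
CUA	L1	23	0.26
CUG	L1	0	0
AUU	I	424	1.86
AUC	I	31	0.14
AUA	M	238	1.76
AUG	M	32	0.24
GUU	V	64	1.74
GUC	V	0	0
GUA	V	81	2.2
GUG	V	2	0.05
UCU	S2	99	2.39
UCC	S2	14	0.34
UCA	S2	99	2.39
UCG	S2	4	0.1
CCU	P	57	1.81
CCC	P	13	0.41
CCA	P	56	1.78
CCG	P	0	0
ACU	T	76	2.14
ACC	T	11	0.31
ACA	T	53	1.49
ACG	T	2	0.06
GCU	A	72	2.44
GCC	A	9	0.31
GCA	A	34	1.15
GCG	A	3	0.1
UAU	Y	153	1.82
UAC	Y	15	0.18
UAA	*	8	2
UAG	*	0	0
CAU	H	62	1.77
CAC	H	8	0.23
CAA	Q	60	1.88
CAG	Q	4	0.13
AAU	N	225	1.75
AAC	N	32	0.25
AAA	K	93	1.69
AAG	K	17	0.31
GAU	D	55	1.83
GAC	D	5	0.17
GAA	E	66	1.71
GAG	E	11	0.29
UGU	C	29	1.76
UGC	C	4	0.24
UGA	W	89	1.87
UGG	W	6	0.13
CGU	R	18	1.38
CGC	R	2	0.15
CGA	R	32	2.46
CGG	R	0	0
AGU	S1	18	0.43
AGC	S1	1	0.02
AGA	S1	97	2.34
AGG	S1	0	0
GGU	G	55	1.11
GGC	G	4	0.08
GGA	G	111	2.23
GGG	G	29	0.58
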