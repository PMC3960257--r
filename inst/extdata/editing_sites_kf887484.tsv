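gene	gene_length	position	codon_ref	codon_alt	aa_ref	aa_alt	conversion	count_A	count_C	count_G	count_U
matK	1536	1258	CAU	UAU	His	Tyr	C-to-U	0	27	0	11
rpoB	3231	398	CGC	CAC	Arg	His	G-to-A	4	0	10	1
rpoC1	2031	603	GAA	GAU	Glu	Asp	A-to-U	19	0	0	7
rpoC1	2031	612	GCG	GCA	Ala	Ala	G-to-A	7	0	22	0
rpoC2	4407	650	AUA	AGA	Ile	Arg	U-to-G	0	0	2	8
atpA	1524	334	UUG	CUG	Leu	Leu	U-to-C	0	13	0	17
atpA	1524	367	AUA	GUA	Ile	Val	A-to-G	23	0	7	0
atpA	1524	933	GAA	GAC	Glu	Asp	A-to-C	41	34	0	0
atpA	1524	1148	UCA	UUA	Ser	Leu	C-to-U	0	2	0	66
ycf3	513	44	UCC	UUC	Ser	Phe	C-to-U	0	0	0	19
rps4	606	588	UAU	UAA	Tyr	stop	U-to-A	55	0	0	28
rps4	606	580	GUG	CUG	Val	Leu	G-to-C	0	55	31	0
rps4	606	370	AAU	GAU	Asn	Asp	A-to-G	4	0	3	0
ndhJ_3UTR	NA	NA	AAU	AAC	Asn	Asn	A-to-C	4	9	0	0
ndhJ	480	480	UGA	UGG	stop	Trp	A-to-G	4	0	9	0
ndhK	738	125	CCA	CUA	Pro	Leu	C-to-U	0	2	0	19
ndhC	363	13	CAC	UAC	His	Tyr	C-to-U	0	3	0	3
psbL	117	111	UUC	UUU	Phe	Phe	C-to-U	0	2	1	10
petL	96	56	CCA	CUA	Pro	Leu	C-to-U	0	0	0	2
rpl20	360	308	UCA	UUA	Ser	Leu	C-to-U	0	5	0	6
psbB	5127	867	AGC	AGU	Ser	Ser	C-to-U	0	25	0	5
petB	648	611	CCA	CUA	Pro	Leu	C-to-U	0	0	0	19
rpoA	1026	527	UCC	UUC	Ser	Phe	C-to-U	0	2	0	9
rps8	411	182	UCA	UUA	Ser	Leu	C-to-U	0	1	0	12
rpl16	411	250	GGC	ACG	Gly	Ser	G-to-A	4	0	2	0
rps3	720	30	UUC	UUU	Phe	Phe	C-to-U	0	6	0	14
ndhD	1503	878	UCA	UUA	Ser	Leu	C-to-U	0	1	0	10
ndhG	531	347	CCA	CUA	Pro	Leu	C-to-U	0	0	0	29
ndhA	1089	722	GCA	GUA	Ala	Val	C-to-U	0	9	0	2
ndhA	1089	474	UCA	UUA	Ser	Leu	C-to-U	0	2	0	17
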