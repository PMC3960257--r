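location	start	end	direction	core_sequence	length	reads	start_ir	end_ir
psbA_5end	1229	1209	R	AACAAGCCTTCTATTATCTA	20	36	NA	NA
trnK-rps16	4378	4356	R	TGTCGTGCCAATCCAACATAAGCC	23	819	NA	NA
psbI-psbD	8129	8150	F	TTCCTTAGACTTAGACCGCGC	21	1200	NA	NA
trnG-trnfM	12314	12333	F	ACCGTATCCCTTACTATTCT	20	1056	NA	NA
trnT_3end	14786	14806	F	GGTTCAAATCCGATAAAGGGC	21	148	NA	NA
rpoB_CDS	21313	21332	F	CGTCGTATATCGCGGAAGCT	20	166	NA	NA
rpoC2-rps2	29130	29147	F	ATTTCAAGCTATTTCGGA	18	20314	NA	NA
atpH_5end	31305	31325	F	ATTGTATCCTTAACCATTTCT	21	34100	NA	NA
atpA_CDS	34274	34297	F	TTATGTACCGCGAACGGCATA	21	1558	NA	NA
psaB_5end	38291	38315	R	AGGAGGATTTGAAAGGCATTA	21	1224	NA	NA
ycf3_3end	41108	41088	R	TTCATTATATCGCTTTCTTCT	21	7428	NA	NA
ycf3_5end	43251	43232	R	TTTGTTTTTATGTTATTTTG	20	450	NA	NA
trnF-ndhJ	47285	47265	R	CTTTGTATCGCGCGCATGACT	21	102512	NA	NA
rbcL_3end_1	55406	55426	F	CTCGGCTCAATCTTTTTTAGA	21	111	NA	NA
rbcL_3end_2	55424	55431	F	AAAAAAAAGATTGAGCCGAAT	21	160	NA	NA
psaI-ycf4	57004	57024	F	TGAATAGAAAGTCAATGTATC	21	120	NA	NA
petA_CDS	59574	59553	R	TTTCACTATATTTCTTACCGGG	22	230	NA	NA
trnP_5end	63758	63739	R	AGGGATGTAGCGCAGCTTGG	20	2740	NA	NA
psbH-petB	70702	70721	F	GGTAGTTCGACCGCGGAATT	20	11965	NA	NA
petD-rpoA	73658	73677	F	TTATTATGATCCATTTCGCG	20	130600	NA	NA
rps19_CDS	80081	80098	F	ATGAATCGCGATTGTATG	18	2770	NA	NA
ndhB_5end_1	87859	87839	R	ACTAATTCATGATCTGGCATG	21	7196	127454	127474
ndhB_5end_2	87863	87843	R	AGTTACTAATTCATGATCTGG	21	5203	127450	127470
rrn16_3end	92921	92941	F	GGTGCGGCTGGATCACCTCCT	21	4056	122393	122373
trnA_intron	95093	95113	F	CTTAGCGGATACTATGATAGC	21	982	120221	120201
trnR_3end	98927	98946	F	GTGTCGGGGGTTCGAATCCC	20	19903	116387	116368
ndhF_CDS	101690	101709	F	ATAACCGCGATTATATGACC	20	1149	NA	NA
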