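locus_id	gene	start	end	fpkm
DeanCp027	ndhC	48846	49209	87311
DeanCp037	psbJ	60890	61013	19529
DeanCp064	rps19	79951	80233	13440
DeanCp043	psaJ	64095	64224	10915
DeanCp002	psbA	83	1145	10274
DeanCp042	petG	63234	63348	9557
DeanCp051	psbN	70154	70286	7916
DeanCp011	petN	17020	17110	7370
DeanCp018	atpF	32063	33432	6499
DeanCp039	psbF	61282	61402	6371
DeanCp038	psbL	61143	61260	4812
DeanCp010	psbM	16638	16743	3750
DeanCp006	psbI	7354	7465	3335
DeanCp050	psbT	69989	70106	3089
DeanCp040	psbE	61412	61664	3020
DeanCp052	psbH	70389	70611	2998
DeanCp020	rps14	35628	35940	2224
DeanCp017	atpH	31349	31595	2138
DeanCp005	psbK	6761	6947	1970
DeanCp009	psbZ	11675	11864	1948
DeanCp030	rbcL	53858	55292	1782
DeanCp007	psbD	8635	9697	1333
DeanCp033	psaI	56726	56837	1308
DeanCp041	petL	62963	63059	1282
DeanCp049	psbB	68293	69820	1197
DeanCp071	ycf68	93397	93832	1096
DeanCp079	psaC	108276	108522	1052
DeanCp019	atpA	33523	35047	971
DeanCp054	petD	72341	73561	956
DeanCp057	rpl36	75472	75586	956
DeanCp044	rpl33	64666	64867	922
DeanCp001	rps12	66870	89475	840
DeanCp021	psaB	36086	38291	676
DeanCp022	psaA	38316	40569	558
DeanCp008	psbC	9644	11066	513
DeanCp084	ndhH	112940	114122	510
DeanCp053	petB	70745	72153	495
DeanCp031	rpl23	55577	55853	419
DeanCp047	rps12	125837	126080	402
DeanCp066	rpl23	81998	82280	400
DeanCp029	atpB	51509	53006	385
DeanCp026	ndhK	48118	48856	342
DeanCp028	atpE	51099	51513	329
DeanCp032	accD	56279	56411	326
DeanCp073	rps15	100781	101054	314
DeanCp076	rpl32	104531	104714	309
DeanCp025	ndhJ	47535	48015	288
DeanCp016	atpI	30197	30941	283
DeanCp074	ndhH	101191	101431	254
DeanCp004	rps16	4488	5567	250
DeanCp080	ndhE	109031	109337	202
DeanCp036	petA	59093	60056	188
DeanCp065	rpl2	80495	81980	185
DeanCp069	ndhB	85606	87851	165
DeanCp070	rps7	88150	88621	159
DeanCp060	rpl14	76697	77069	152
DeanCp023	ycf3	41199	43189	152
DeanCp068	ycf15	83879	84167	149
DeanCp045	rps18	65145	65658	144
DeanCp058	infA	75691	76042	144
DeanCp046	rpl20	65815	66175	144
DeanCp024	rps4	44159	44765	142
DeanCp048	clpP	67131	67782	141
DeanCp081	ndhG	109549	110080	136
DeanCp034	ycf4	57149	57707	134
DeanCp003	matK	1685	3221	133
DeanCp061	rpl16	77186	78490	132
DeanCp059	rps8	76143	76554	128
DeanCp063	rpl22	79429	79873	113
DeanCp035	cemA	58162	58861	110
DeanCp075	ndhF	101464	103684	102
DeanCp077	ccsA	105547	106507	87
DeanCp082	ndhI	110198	110741	85
DeanCp055	rpoA	73770	74796	74
DeanCp014	rpoC2	24536	28943	66
DeanCp015	rps2	29236	29947	62
DeanCp083	ndhA	110838	112939	58
DeanCp078	ndhD	106654	108157	57
DeanCp072	ycf1	99622	100414	52
DeanCp056	rps11	74860	75292	48
DeanCp062	rps3	78636	79356	44
DeanCp067	ycf2	82674	83874	39
DeanCp090	ycf2	131435	132638	39
DeanCp013	rpoC1	22302	24333	31
DeanCp012	rpoB	19034	22265	29
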