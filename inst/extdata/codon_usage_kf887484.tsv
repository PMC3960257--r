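codon	count	trna
UUU	790	NA
UUC	448	trnF-GAA
UUA	790	trnL-UAA
UUG	445	trnL-CAA
CUU	492	NA
CUC	226	NA
CUA	363	trnL-UAG
CUG	150	NA
AUU	874	NA
AUC	379	trnI-GAU
AUA	562	trnI-CAU
AUG	522	trn(f)M-CAU
GUU	473	NA
GUC	182	trnV-GAC
GUA	505	trnV-UAC
GUG	196	NA
UCU	458	NA
UCC	328	trnS-GGA
UCA	296	trnS-UGA
UCG	161	NA
CCU	375	NA
CCC	243	NA
CCA	291	trnP-UGG
CCG	151	NA
ACU	507	NA
ACC	236	trnT-GGU
ACA	331	trnT-UGU
ACG	173	NA
GCU	593	NA
GCC	242	NA
GCA	413	trnA-UGC
GCG	202	NA
UAU	599	NA
UAC	211	trnY-GUA
UAA	48	NA
UAG	20	NA
CAU	371	NA
CAC	164	trnH-GUG
CAA	572	trnQ-GUU
CAG	235	NA
AAU	647	NA
AAC	274	trnN-GUU
AAA	865	trnK-UUU
AAG	367	NA
GAU	619	NA
GAC	209	trnD-GUC
GAA	807	trnE-UUC
GAG	372	NA
UGU	215	NA
UGC	106	trnC-GCA
UGA	17	NA
UGG	430	trnW-CCA
CGU	312	trnR-ACG
CGC	152	NA
CGA	311	NA
CGG	152	NA
AGA	436	trnR-UCU
AGG	221	NA
AGU	349	NA
AGC	176	trnS-GCU
GGU	539	NA
GGC	225	trnG-GCC
GGA	653	trnG-UCC
GGG	359	NA
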