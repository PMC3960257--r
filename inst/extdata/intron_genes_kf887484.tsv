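gene	region	exon1	intron1	exon2	intron2	exon3	trans_spliced
rps16	LSC	40	830	209	NA	NA	FALSE
atpF	LSC	159	802	408	NA	NA	FALSE
ycf3	LSC	126	749	228	728	159	FALSE
petB	LSC	6	760	642	NA	NA	FALSE
petD	LSC	9	686	525	NA	NA	FALSE
rpl16	LSC	9	893	402	NA	NA	FALSE
rps12	LSC	117	NA	231	NA	NA	TRUE
rpl2	IR	393	660	432	NA	NA	FALSE
ndhB	IR	777	712	756	NA	NA	FALSE
ndhA	SSC	549	1012	540	NA	NA	FALSE
trnK-UUU	LSC	38	2486	33	NA	NA	FALSE
trnL-UAA	LSC	37	537	50	NA	NA	FALSE
trnV-UAC	LSC	39	605	37	NA	NA	FALSE
trnI-GAU	IR	42	801	35	NA	NA	FALSE
trnA-UGC	IR	38	811	35	NA	NA	FALSE
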