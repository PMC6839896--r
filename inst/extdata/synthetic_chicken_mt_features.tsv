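name	ftype	start	end	strand	codon_start
D-loop	D-loop	1	1227	+	NA
tRNA-Phe	tRNA	1228	1296	+	NA
rrnS	rRNA	1297	2271	+	NA
tRNA-Val	tRNA	2272	2344	+	NA
rrnL	rRNA	2345	3965	+	NA
tRNA-Leu1	tRNA	3966	4040	+	NA
ND1	CDS	4041	5015	+	1
tRNA-Ile	tRNA	5016	5086	+	NA
tRNA-Gln	tRNA	5087	5157	-	NA
tRNA-Met	tRNA	5158	5226	+	NA
ND2	CDS	5241	6281	+	1
tRNA-Trp	tRNA	6282	6356	+	NA
tRNA-Ala	tRNA	6357	6428	-	NA
tRNA-Asn	tRNA	6429	6501	-	NA
tRNA-Cys	tRNA	6502	6567	-	NA
tRNA-Tyr	tRNA	6568	6637	-	NA
COX1	CDS	6638	8182	+	1
tRNA-Ser2	tRNA	8183	8254	-	NA
tRNA-Asp	tRNA	8255	8322	+	NA
COX2	CDS	8331	9014	+	1
tRNA-Lys	tRNA	9015	9082	+	NA
ATP8	CDS	9084	9251	+	1
ATP6	CDS	9242	9925	+	1
COX3	CDS	9926	10711	+	1
tRNA-Gly	tRNA	10712	10780	+	NA
ND3	CDS	10781	11131	+	1
tRNA-Arg	tRNA	11132	11200	+	NA
ND4L	CDS	11201	11497	+	1
ND4	CDS	11498	12874	+	1
tRNA-His	tRNA	12875	12943	+	NA
tRNA-Ser1	tRNA	12944	13010	+	NA
tRNA-Leu2	tRNA	13011	13081	+	NA
ND5	CDS	13082	14899	+	1
CYTB	CDS	14900	16042	+	1
tRNA-Thr	tRNA	16043	16113	+	NA
tRNA-Pro	tRNA	16114	16184	-	NA
ND6	CDS	16185	16706	-	1
tRNA-Glu	tRNA	16707	16775	-	NA
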