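mutation_type	region	n	heteroplasmic	transition	transversion
NC	D-loop	15	12	15	0
NC	rRNA	5	3	4	1
NC	tRNA	2	2	2	0
NC	intergene	2	1	2	0
NS	COX1	1	1	1	0
NS	COX2	2	1	2	0
NS	ND4	1	0	0	1
NS	CYTB	2	1	2	0
S	ND1	1	1	1	0
S	ND2	1	0	1	0
S	COX1	3	3	3	0
S	COX2	1	1	1	0
S	COX3	3	2	3	0
S	ATP6	3	3	3	0
S	ND3	2	2	2	0
S	ND4L	1	1	1	0
S	ND4	5	4	5	0
S	ND5	2	1	2	0
S	CYTB	1	1	1	0
S	ND6	3	3	3	0
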