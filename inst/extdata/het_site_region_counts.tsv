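mutation_type	region	n	non_polymorphic	polymorphic	transition	transversion
NC	D-loop	130	118	12	108	22
NC	rRNA	5	2	3	4	1
NC	tRNA	2	0	2	2	0
NC	intergene	1	0	1	1	0
NS	COX1	2	1	1	2	0
NS	COX2	3	2	1	2	1
NS	ATP6	4	4	0	4	0
NS	ND5	2	2	0	0	2
NS	CYTB	1	0	1	1	0
NS	ND6	3	3	0	1	2
S	ND1	1	0	1	1	0
S	COX1	3	0	3	3	0
S	COX2	1	0	1	1	0
S	ATP6	4	1	3	4	0
S	COX3	2	0	2	2	0
S	ND3	2	0	2	2	0
S	ND4L	1	0	1	1	0
S	ND4	4	0	4	4	0
S	ND5	1	0	1	1	0
S	CYTB	2	1	1	2	0
S	ND6	4	1	3	3	1
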