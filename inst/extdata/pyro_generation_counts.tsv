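site	population	generation	n	heteroplasmic
mt.T5718G	R	F0	26	15
mt.T5718G	S	F0	24	9
mt.T5718G	RR	F1	27	0
mt.T5718G	RS	F1	14	0
mt.T5718G	SS	F1	23	1
mt.T5718G	SR	F1	33	1
mt.T5718G	SG	F1	6	2
mt.A5694T	R	F0	26	15
mt.A5694T	S	F0	24	11
mt.A5694T	RR	F1	27	2
mt.A5694T	RS	F1	14	1
mt.A5694T	SS	F1	23	1
mt.A5694T	SR	F1	33	1
mt.A5694T	SG	F1	6	2
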