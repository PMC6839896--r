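name	forward	reverse	expected_length
PW	GTTGCGTCCTATCCTAGTCCTCTCG	GCAGGTGTAGTCCAGGCTTCACTT	16775
P8682	AAACACCGTAGATGCCCAAG	TAGGGGGAGGTCTGTTGTTG	232
P16121	TCCACCCTTCTTAGAGTATCAG	TGGGTGAGGTTTGTTGTTAG	176
PND2	CCTCCTCCTAACATCACAGTCTCTTAA	AGAAGGCTAGGATTTTTCGTGTTTGT	122
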