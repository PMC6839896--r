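site	genotype	stratum	count
mt.G8682A	AA	LH	0
mt.G8682A	AA	PR	0
mt.G8682A	AA	TB	0
mt.G8682A	AA	BY	0
mt.G8682A	AA	SK	0
mt.G8682A	GA	LH	0
mt.G8682A	GA	PR	0
mt.G8682A	GA	TB	0
mt.G8682A	GA	BY	0
mt.G8682A	GA	SK	1
mt.G8682A	GG	LH	10
mt.G8682A	GG	PR	10
mt.G8682A	GG	TB	10
mt.G8682A	GG	BY	10
mt.G8682A	GG	SK	9
mt.G16121A	AA	LH	5
mt.G16121A	AA	PR	1
mt.G16121A	AA	TB	9
mt.G16121A	AA	BY	10
mt.G16121A	AA	SK	8
mt.G16121A	GA	LH	0
mt.G16121A	GA	PR	0
mt.G16121A	GA	TB	0
mt.G16121A	GA	BY	0
mt.G16121A	GA	SK	2
mt.G16121A	GG	LH	5
mt.G16121A	GG	PR	9
mt.G16121A	GG	TB	1
mt.G16121A	GG	BY	0
mt.G16121A	GG	SK	0
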