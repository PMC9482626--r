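FAM1	GF	0	0	1	2
FAM1	GM	0	0	2	1
FAM1	FA	GF	GM	1	2
FAM1	UN	GF	GM	1	1
FAM1	MO	0	0	2	1
FAM1	DA	FA	MO	2	2
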