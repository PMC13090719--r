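name	recognition	cut_top	cut_bottom
BtsI	GCAGTG	2	0
BsrDI	GCAATG	2	0
SapI	GCTCTTC	1	4
BspQI	GCTCTTC	1	4
BsaI	GGTCTC	1	5
BbsI	GAAGAC	2	6
BsmBI	CGTCTC	1	5
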