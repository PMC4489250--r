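A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
0	0	0.5	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
0	0	0.5	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
0	0	0.5	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
0	0	0.5	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
0	0	0.5	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
0	0	0.5	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
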