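residue	aa
20	G
27	F
31	G
33	G
35	G
40	G
53	L
55	V
57	W
66	Y
67	G
91	G
96	R
102	D
104	G
127	G
130	F
134	G
136	I
196	P
222	E
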