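node	snp_id	ancestral	derived
A-M91	M91	T	C
F-M89	M89	C	T
F-M89	P14	G	A
C-M130	M130	C	T
E1b-M215	M215	A	G
GH-F871	F871	G	C
G-M201	M201	G	T
H-M69	M69	T	C
IJK-S137	S137	A	G
IJK-S137	M523	T	A
I-M170	M170	A	C
I-M170	P38	A	C
I1-M253	M253	C	T
I2-M223	M223	G	A
J-M304	M304	A	C
J1-M267	M267	T	G
J2-M172	M172	T	G
K2-M526	M526	G	A
NO-M214	M214	A	C
P-M45	M45	G	A
P-M45	M74	G	A
Q-M242	M242	C	T
R-M207	M207	A	G
R-M207	M306	C	A
R1a-M420	M420	A	T
R1b-M343	M343	C	A
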