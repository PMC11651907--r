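0	A	B
20	A	B
40	A	B
100	C	D
120	C	D
140	C	D
200	E	F
220	E	F
240	E	F
86400	A	B
86420	A	B
86440	A	B
86500	G	H
86520	G	H
86540	G	H
86600	I	J
86620	I	J
86640	I	J
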