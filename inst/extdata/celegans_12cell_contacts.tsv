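# divdec embryo contacts
stage	cell_a	cell_b
12-cell	ABala	ABalp
12-cell	ABala	ABara
12-cell	ABalp	ABarp
12-cell	ABalp	MS
12-cell	ABara	ABarp
12-cell	ABarp	C
12-cell	ABarp	ABpra
12-cell	ABpla	ABplp
12-cell	ABpla	ABala
12-cell	ABplp	ABpra
12-cell	ABplp	MS
12-cell	ABpra	C
12-cell	ABpra	ABprp
12-cell	ABprp	C
12-cell	MS	E
12-cell	E	P3
12-cell	C	P3
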