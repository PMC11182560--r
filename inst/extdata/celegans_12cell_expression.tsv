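# divdec embryo expression states
cell	stage	state
ABala	12-cell	aba
ABalp	12-cell	aba
ABara	12-cell	aba
ABarp	12-cell	aba
ABpla	12-cell	ab
ABplp	12-cell	ab
ABpra	12-cell	ab
ABprp	12-cell	ab
MS	12-cell	ms
E	12-cell	e
C	12-cell	c
P3	12-cell	p3
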