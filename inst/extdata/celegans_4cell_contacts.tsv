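# divdec embryo contacts
stage	cell_a	cell_b
4-cell	ABa	ABp
4-cell	ABa	EMS
4-cell	ABp	EMS
4-cell	ABp	P2
4-cell	EMS	P2
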