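# divdec embryo expression states
cell	stage	state
ABa	4-cell	ab
ABp	4-cell	ab
EMS	4-cell	ems
P2	4-cell	p2
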