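# divdec two-gene initial states
init	gA	gB
10	1	0
01	0	1
11	1	1
00	0	0
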