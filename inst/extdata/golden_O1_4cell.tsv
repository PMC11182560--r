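# divdec tissue generation=3
position	lineage_id	g1
1	7	1
2	6	0
3	4	0
4	5	1
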