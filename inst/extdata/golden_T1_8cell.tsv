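# divdec tissue generation=4
position	lineage_id	g1	g2
1	15	1	1
2	14	1	0
3	13	0	1
4	12	0	0
5	8	0	0
6	9	0	1
7	10	1	0
8	11	1	1
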