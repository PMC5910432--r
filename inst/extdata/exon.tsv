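gene_id	position_index	signal
g1	1	100
g1	2	1000
g2	1	1000
g2	2	100
g3	1	5
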