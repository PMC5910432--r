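gene_id	FF_1	FF_2	FF_3	PE_1	PE_2	PE_3
g1	10	20	10	3	9	3
g2	10	20	10	9	3	9
g3	4	4	4	8	8	8
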