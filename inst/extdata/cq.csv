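# reference=Gapdh
gene_id,replicate,cq
Gapdh,1,20
Gapdh,2,20
Gapdh,3,20
GeneX,1,25
GeneX,2,25
GeneX,3,25
GeneY,1,18
GeneY,2,18
GeneY,3,18
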