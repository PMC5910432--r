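size_nt,fluorescence
25,0
100,0
200,2
300,0
2000,0
4000,0
6000,0
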