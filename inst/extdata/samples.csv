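# scale=linear
sample_id,group,replicate_index
FF_1,FF,1
FF_2,FF,2
FF_3,FF,3
PE_1,FFPE,1
PE_2,FFPE,2
PE_3,FFPE,3
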