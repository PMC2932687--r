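chrom,start,end,feature,assembly
chrIII,12077862,12077884,mir57_seed_site,WS205
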