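feature,start,end
promoter,-2260,-1
lag1_site,-61,-55
stem_loop,-20,80
mature,1,24
construct_full,-2260,234
construct_promoter_only,-2260,-63
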