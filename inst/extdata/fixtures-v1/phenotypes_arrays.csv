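genotype,condition,assay,pct,n
Pmir57_mir57_wt,20C,VabNob,29.3,625
Pmir57_only_wt,20C,VabNob,33.9,373
Pmir57_mir57_gk175,20C,VabNob,36.4,522
Pmir57_only_gk175,20C,VabNob,0,583
Pvab7_mir57_wt,20C,VabNob,11.3,362
Pvab7_mir57m_wt,20C,VabNob,0,347
Pvab7_only_wt,20C,VabNob,0,831
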