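group,gene,replicate,ct
wt,gpd-1,1,15
wt,gpd-1,2,15
wt,gpd-1,3,15
wt,nob-1a,1,22
wt,nob-1a,2,22
wt,nob-1a,3,22
wt,nob-1b,1,24
wt,nob-1b,2,24
wt,nob-1b,3,24
mir57del,gpd-1,1,15
mir57del,gpd-1,2,15
mir57del,gpd-1,3,15
mir57del,nob-1a,1,22
mir57del,nob-1a,2,22
mir57del,nob-1a,3,22
mir57del,nob-1b,1,23
mir57del,nob-1b,2,23
mir57del,nob-1b,3,23
wt_array,gpd-1,1,15
wt_array,gpd-1,2,15
wt_array,gpd-1,3,15
wt_array,nob-1a,1,22
wt_array,nob-1a,2,22
wt_array,nob-1a,3,22
wt_array,nob-1b,1,26
wt_array,nob-1b,2,26
wt_array,nob-1b,3,26
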