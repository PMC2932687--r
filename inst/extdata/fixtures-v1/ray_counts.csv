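group,rays
wt,6
wt,6
wt,7
wt,7
wt,7
wt,7
wt,7
wt,7
wt,7
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,8
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,9
wt,10
wt,10
wt,10
wt,10
wt,10
wt,10
wt,10
wt,10
wt,10
wt,10
wt,10
wt,10
wt,11
wt,11
mir57_promoter_array,1
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,2
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,3
mir57_promoter_array,4
mir57_promoter_array,4
mir57_promoter_array,4
mir57_promoter_array,4
mir57_promoter_array,4
mir57_promoter_array,4
mir57_promoter_array,4
mir57_promoter_array,4
mir57_promoter_array,5
mir57_promoter_array,5
mir57_promoter_array,5
mir57_promoter_array,5
mir57_promoter_array,5
mir57_promoter_array,6
mir57_gk175_synthetic,6
mir57_gk175_synthetic,6
mir57_gk175_synthetic,6
mir57_gk175_synthetic,7
mir57_gk175_synthetic,7
mir57_gk175_synthetic,7
mir57_gk175_synthetic,8
mir57_gk175_synthetic,8
mir57_gk175_synthetic,8
mir57_gk175_synthetic,8
mir57_gk175_synthetic,8
mir57_gk175_synthetic,8
mir57_gk175_synthetic,8
mir57_gk175_synthetic,8
mir57_gk175_synthetic,8
mir57_gk175_synthetic,8
mir57_gk175_synthetic,9
mir57_gk175_synthetic,9
mir57_gk175_synthetic,9
mir57_gk175_synthetic,9
mir57_gk175_synthetic,9
mir57_gk175_synthetic,9
mir57_gk175_synthetic,9
mir57_gk175_synthetic,10
mir57_gk175_synthetic,10
mir57_gk175_synthetic,10
mir57_gk175_synthetic,10
mir57_gk175_synthetic,10
mir57_gk175_synthetic,10
mir57_gk175_synthetic,10
mir57_gk175_synthetic,10
mir57_gk175_synthetic,11
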