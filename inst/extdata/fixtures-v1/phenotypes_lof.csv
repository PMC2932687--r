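genotype,condition,assay,pct,n
mir-57(gk175),15C,Emb,1.6,514
mir-57(gk175),15C,Lva,0.5,325
mir-57(gk175),15C,Ste,2.7,339
mir-57(gk175),20C,Emb,1.3,840
mir-57(gk175),20C,Lva,2,359
mir-57(gk175),20C,Ste,5.3,472
mir-57(gk175),26C,Emb,6.7,892
mir-57(gk175),26C,Lva,5.6,841
mir-57(gk175),26C,Ste,32.1,978
N2,15C,Emb,1.2,277
N2,15C,Lva,0.8,363
N2,15C,Ste,0,710
N2,20C,Emb,0.7,647
N2,20C,Lva,0.5,451
N2,20C,Ste,1.2,389
N2,26C,Emb,1.3,360
N2,26C,Lva,1.5,399
N2,26C,Ste,5.7,451
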