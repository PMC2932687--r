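{
  "version": "fixtures-v1",
  "files": {
    "canonical_lineage.csv": "synthetic timings calibrated to printed stage landmarks (4-, 100-, 200-cell)",
    "mir57_locus_features.csv": "feature geometry from the published locus figure (CSL site edge -55, gk175 414 bp); coordinates partly synthetic",
    "nob1b_utr_site.csv": "published absolute interval of the UTR seed site",
    "mir57_locus.synthetic.fa": "synthetic backbone; mature = reverse complement of the published probe; CSL site planted at -61..-55",
    "phenotypes_lof.csv": "printed percentage/n pairs; animal-level records are rebuilt in code with nearest integer counts",
    "phenotypes_arrays.csv": "printed percentage/n pairs; animal-level records are rebuilt in code with nearest integer counts",
    "ray_counts.csv": "wt and array groups match printed summaries; gk175 group synthetic",
    "qpcr_ct.synthetic.csv": "synthetic Cts emulating reported fold-change directions"
  }
}
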