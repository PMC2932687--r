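Package: lintrex
Title: Lineage-Resolved Reporter Expression Analysis for C. elegans Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping fluorescent reporter intensities onto the
    invariant C. elegans embryonic cell lineage. Assembles lineage trees from
    tracked-nuclei tables by merging forward tracing with backward tracing from
    late-stage expressing cells, normalizes division timing onto a canonical
    (Sulston-style) lineage, interpolates expression onto a common time grid,
    calls expressing cells and onset stages, summarizes expressing sublineages,
    and compares RNAi-treated with control embryos. Includes supporting
    regulatory-sequence utilities (miRNA seed-match and IUPAC motif scanning in
    mature-miRNA-anchored coordinates, deletion alleles) and bench-statistics
    helpers (phenotype penetrance, delta-delta-Ct fold changes, band ratios,
    ROI quantification), together with a fully ground-truthed synthetic embryo
    simulator used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rlang,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
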