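#' @title Packaged fixtures
#' @description Worked-example data distilled from the published record of
#'   the mir-57 / nob-1 system: expression trees for the two reporters on
#'   the canonical lineage (four ABp(l/r)(a/p)p posterior sublineages plus
#'   posterior C for the miRNA reporter, onset at the 200-cell stage; the
#'   same AB sublineages plus posterior E for the Hox reporter, onset at
#'   the 100-cell stage), the miRNA locus annotation (stem-loop, mature
#'   sequence, CSL/LAG-1 site 55 bp upstream, the 414-bp gk175 deletion,
#'   construct intervals), reconstructed phenotype-penetrance tables, and
#'   tail-ray counts. Values the published tables print are encoded as
#'   printed; everything else is synthetic and labelled so in the fixture
#'   manifest and file names.
#' @name fixtures
NULL

.fixture_genes <- list(
  "mir-57" = list(roots = c("ABplapp", "ABplppp", "ABprapp", "ABprppp",
                            "Cap", "Cpp"),
                  onset_stage = 200, channel = "red"),
  "nob-1" = list(roots = c("ABplapp", "ABplppp", "ABprapp", "ABprppp", "Ep"),
                 onset_stage = 100, channel = "green")
)

#' Packaged expression-tree fixture for a reporter
#'
#' A noise-free tracked tree on canonical timing: every cell of the
#' canonical lineage alive in the imaging window, with the reporter
#' channel at background (100) everywhere and background + 400 in the
#' expressing sublineages from the frame at which the live count first
#' reaches the configured onset stage.
#'
#' @param gene "mir-57" or "nob-1".
#' @param end_time last imaged minute (default 215, around comma stage).
#' @return list: `tree` (named `tracked_tree`), `timings` (exact canonical
#'   timings of the covered cells), `roots`, `onset_frame`, `channel`.
#' @export
fixture_expression_tree <- function(gene = c("mir-57", "nob-1"),
                                    end_time = 215) {
  gene <- match.arg(gene)
  spec <- .fixture_genes[[gene]]
  can <- canonical_lineage()
  onset_f <- time_at_stage(can, spec$onset_stage)
  stopifnot(onset_f == round(onset_f))  # landmark minutes are integral

  open_end <- can$terminal & !can$death
  f0 <- pmax(1, ceiling(can$birth_min - 1e-9))
  f1 <- ifelse(open_end, floor(can$end_min + 1e-9),
               ceiling(can$end_min - 1e-9) - 1)
  f1 <- pmin(f1, end_time)
  keep <- which(f0 <= f1)

  nm <- can$name[keep]
  idx <- stats::setNames(seq_along(keep), nm)
  parent <- rep(NA_integer_, length(keep))
  for (j in seq_along(keep)) {
    if (nm[j] == "P0") next
    mo <- mother_of(nm[j])
    if (!is.na(idx[mo])) parent[j] <- unname(idx[mo])
  }
  cells <- data.frame(cell_id = seq_along(keep), parent_id = parent,
                      name = nm, birth_tp = f0[keep], end_tp = f1[keep],
                      stringsAsFactors = FALSE)

  expr <- .under_roots(nm, spec$roots)
  recs <- lapply(seq_along(keep), function(j) {
    f <- seq(cells$birth_tp[j], cells$end_tp[j])
    val <- 100 + ifelse(expr[j] & f >= onset_f, 400, 0)
    data.frame(time = f, id = j, x = 0, y = 0, z = 0, diameter = 3,
               name = nm[j],
               red = if (spec$channel == "red") val else 300,
               green = if (spec$channel == "green") val else 300,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, recs)
  rec <- rec[order(rec$time, rec$id), ]
  rownames(rec) <- NULL
  rec$cell_id <- rec$id
  tree <- new_tracked_tree(cells, rec)
  timings <- data.frame(name = nm, birth_min = can$birth_min[keep],
                        end_min = can$end_min[keep],
                        terminal = can$terminal[keep],
                        stringsAsFactors = FALSE)
  list(tree = tree, timings = timings, roots = spec$roots,
       onset_frame = onset_f, channel = spec$channel, gene = gene)
}

#' Run the expression-calling pipeline on a packaged fixture
#'
#' @param fx fixture from [fixture_expression_tree()] (or a gene name).
#' @param k,min_run,purity pipeline parameters.
#' @return list: `series`, `calls` (with onset stages on the canonical
#'   lineage), `summary` (`sublineage_summary`), `warp`.
#' @export
fixture_pipeline <- function(fx, k = 2, min_run = 5, purity = 0.8) {
  if (is.character(fx)) fx <- fixture_expression_tree(fx)
  can <- canonical_lineage()
  ser <- background_subtract(extract_series(fx$tree, fx$channel), k = k)
  calls <- call_expression(ser, min_run = min_run,
                           stage_fun = function(t) stage_at(can, t))
  summ <- summarize_sublineages(calls, fx$tree, purity = purity)
  warp <- fit_warp(fx$timings, can)
  list(series = ser, calls = calls, summary = summ, warp = warp)
}

#' Packaged mir-57 locus fixture
#'
#' Locus annotation in mature-anchored coordinates: promoter (-2260..-1),
#' CSL/LAG-1 consensus site with its downstream edge 55 bp upstream of the
#' mature start, stem-loop, 24-nt mature sequence, the two injection
#' construct intervals (-2260..+234 and -2260..-63), and the gk175
#' deletion allele (-180..+234, 414 bp, removing the entire stem-loop).
#' The mature sequence is the reverse complement of the published
#' detection probe; the surrounding sequence is synthetic (fixed internal
#' generator) with the CSL site planted so the motif scan has exactly one
#' forward-strand hit.
#'
#' @return list: `locus` (`locus_annotation`), `gk175`
#'   (`deletion_allele`), `sequence` (promoter + locus, one string),
#'   `anchor` (1-based index of anchored +1 in `sequence`),
#'   `lag1_consensus`, `mature`, `nob1b_site` (absolute-coordinate
#'   annotation of the published UTR site).
#' @export
mir57_locus_fixture <- function() {
  span <- anchored_interval(-2260, 300)
  seq_len_total <- interval_length(span)          # 2560
  anchor <- 2261                                  # index of +1
  idx_of <- function(p) ifelse(p < 0, p + anchor, p + anchor - 1)

  mature <- reverse_complement("ACACACAGCTCGATCTACAGGGTA")
  lag1 <- "RTGGGAA"

  # deterministic synthetic backbone, independent of the caller's RNG
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(5751L)
  base <- sample(c("A", "C", "G", "T"), seq_len_total, replace = TRUE)
  plant <- function(base, at, s) {
    base[seq(at, at + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    base
  }
  base <- plant(base, idx_of(-61), "ATGGGAA")
  base <- plant(base, idx_of(1), mature)
  # scrub accidental extra motif matches (keep only the planted site)
  repeat {
    s <- paste(base, collapse = "")
    hits <- scan_motif(s, lag1)
    extra <- hits[hits$start != idx_of(-61), , drop = FALSE]
    if (!nrow(extra)) break
    for (i in seq_len(nrow(extra))) {
      base[extra$start[i]] <- "C"
    }
  }
  sequence <- paste(base, collapse = "")

  features <- data.frame(
    feature = c("promoter", "lag1_site", "stem_loop", "mature",
                "construct_full", "construct_promoter_only"),
    start = c(-2260, -61, -20, 1, -2260, -2260),
    end = c(-1, -55, 80, 24, 234, -63),
    stringsAsFactors = FALSE
  )
  list(locus = locus_annotation(span, features),
       gk175 = deletion_allele("gk175", -180, 234),
       sequence = sequence, anchor = anchor,
       lag1_consensus = lag1, mature = mature,
       nob1b_site = data.frame(chrom = "chrIII", start = 12077862,
                               end = 12077884, feature = "mir57_seed_site",
                               assembly = "WS205"))
}

# printed percentage cells of the phenotype tables: pct, n
.table1_cells <- data.frame(
  genotype = rep(c("mir-57(gk175)", "N2"), each = 9),
  condition = rep(rep(c("15C", "20C", "26C"), each = 3), 2),
  assay = rep(c("Emb", "Lva", "Ste"), 6),
  pct = c(1.6, 0.5, 2.7, 1.3, 2.0, 5.3, 6.7, 5.6, 32.1,
          1.2, 0.8, 0.0, 0.7, 0.5, 1.2, 1.3, 1.5, 5.7),
  n = c(514, 325, 339, 840, 359, 472, 892, 841, 978,
        277, 363, 710, 647, 451, 389, 360, 399, 451),
  stringsAsFactors = FALSE
)

.table2_cells <- data.frame(
  genotype = c("Pmir57_mir57_wt", "Pmir57_only_wt", "Pmir57_mir57_gk175",
               "Pmir57_only_gk175", "Pvab7_mir57_wt", "Pvab7_mir57m_wt",
               "Pvab7_only_wt"),
  condition = "20C",
  assay = "VabNob",
  pct = c(29.3, 33.9, 36.4, 0, 11.3, 0, 0),
  n = c(625, 373, 522, 583, 362, 347, 831),
  stringsAsFactors = FALSE
)

.cells_to_records <- function(cells) {
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n[i]
    # nearest integer count to the printed percentage
    affected <- round(cells$pct[i] * n / 100)
    flag <- c(rep(TRUE, affected), rep(FALSE, n - affected))
    out <- data.frame(animal = seq_len(n), genotype = cells$genotype[i],
                      condition = cells$condition[i], assay = cells$assay[i],
                      stringsAsFactors = FALSE)
    out[[cells$assay[i]]] <- flag
    out
  })
  all_flags <- unique(cells$assay)
  rows <- lapply(rows, function(df) {
    for (f in all_flags) if (is.null(df[[f]])) df[[f]] <- NA
    df
  })
  do.call(rbind, rows)
}

#' Reconstructed phenotype-penetrance fixtures
#'
#' Animal-level records rebuilt from the printed percentage/n pairs of the
#' loss-of-function table (Emb/Lva/Ste by temperature) and the transgenic
#' array table (Vab/Nob by construct), using the nearest integer affected
#' count per cell. Each phenotype was scored on its own animal cohort, so
#' records carry an `assay` column.
#'
#' @return list with `table1` and `table2` record data.frames.
#' @export
phenotype_fixtures <- function() {
  list(table1 = .cells_to_records(.table1_cells),
       table2 = .cells_to_records(.table2_cells))
}

#' @rdname phenotype_fixtures
#' @export
phenotype_fixture_cells <- function() {
  list(table1 = .table1_cells, table2 = .table2_cells)
}

#' Tail-ray count fixtures
#'
#' Integer per-side ray counts constructed to reproduce the printed
#' summaries: wild type 8.6±1.2 (n = 57) and promoter-array males
#' 3.2±1.2 (n = 38). The deletion-mutant group (n = 32, no printed
#' summary) is synthetic.
#'
#' @return data.frame: `group`, `rays`.
#' @export
ray_count_fixtures <- function() {
  wt <- c(6, 6, rep(7, 7), rep(8, 19), rep(9, 15), rep(10, 12), 11, 11)
  arr <- c(1, rep(2, 11), rep(3, 12), rep(4, 8), rep(5, 5), 6)
  gk <- c(6, 6, 6, 7, 7, 7, rep(8, 10), rep(9, 7), rep(10, 8), 11)
  data.frame(group = c(rep("wt", length(wt)),
                       rep("mir57_promoter_array", length(arr)),
                       rep("mir57_gk175_synthetic", length(gk))),
             rays = c(wt, arr, gk), stringsAsFactors = FALSE)
}

#' Synthetic qPCR Ct fixture
#'
#' Noise-free triplicate Ct values emulating the reported directions of
#' the Hox-transcript assay: the b-form transcript doubles in the miRNA
#' deletion and drops about four-fold under the promoter array, the
#' a-form is unchanged, all relative to the GAPDH reference gpd-1.
#'
#' @return data.frame: `group`, `gene`, `replicate`, `ct`.
#' @export
qpcr_fixture <- function() {
  grid <- expand.grid(replicate = 1:3,
                      gene = c("gpd-1", "nob-1a", "nob-1b"),
                      group = c("wt", "mir57del", "wt_array"),
                      stringsAsFactors = FALSE)
  base_ct <- c("gpd-1" = 15, "nob-1a" = 22, "nob-1b" = 24)
  shift <- function(group, gene) {
    if (gene != "nob-1b") return(0)
    switch(group, wt = 0, mir57del = -1, wt_array = 2)
  }
  grid$ct <- mapply(function(g, gene) base_ct[[gene]] + shift(g, gene),
                    grid$group, grid$gene)
  grid[, c("group", "gene", "replicate", "ct")]
}

#' Write all file-backed fixtures
#'
#' Writes the canonical lineage CSV, the locus feature/sequence files and
#' the phenotype, ray-count and qPCR tables (with a provenance manifest)
#' to a versioned fixture directory.
#'
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
build_fixtures <- function(dir = "fixtures-v1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_canonical_lineage(canonical_lineage(), p("canonical_lineage.csv"))
  lf <- mir57_locus_fixture()
  utils::write.csv(lf$locus$features, p("mir57_locus_features.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(lf$nob1b_site, p("nob1b_utr_site.csv"),
                   row.names = FALSE, quote = FALSE)
  write_fasta(c(mir57_locus_synthetic = lf$sequence),
              p("mir57_locus.synthetic.fa"))
  cells <- phenotype_fixture_cells()
  utils::write.csv(cells$table1, p("phenotypes_lof.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cells$table2, p("phenotypes_arrays.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ray_count_fixtures(), p("ray_counts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(qpcr_fixture(), p("qpcr_ct.synthetic.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    version = "fixtures-v1",
    files = list(
      canonical_lineage.csv = "synthetic timings calibrated to printed stage landmarks (4-, 100-, 200-cell)",
      mir57_locus_features.csv = "feature geometry from the published locus figure (CSL site edge -55, gk175 414 bp); coordinates partly synthetic",
      nob1b_utr_site.csv = "published absolute interval of the UTR seed site",
      mir57_locus.synthetic.fa = "synthetic backbone; mature = reverse complement of the published probe; CSL site planted at -61..-55",
      phenotypes_lof.csv = "printed percentage/n pairs; animal-level records are rebuilt in code with nearest integer counts",
      phenotypes_arrays.csv = "printed percentage/n pairs; animal-level records are rebuilt in code with nearest integer counts",
      ray_counts.csv = "wt and array groups match printed summaries; gk175 group synthetic",
      qpcr_ct.synthetic.csv = "synthetic Cts emulating reported fold-change directions"
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Path to a shipped fixture file
#'
#' @param file file name within the versioned fixture directory.
#' @return absolute path.
#' @export
fixture_path <- function(file) {
  p <- system.file("extdata", "fixtures-v1", file, package = "lintrex")
  if (!nzchar(p)) stop("fixture file not shipped: ", file, call. = FALSE)
  p
}
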