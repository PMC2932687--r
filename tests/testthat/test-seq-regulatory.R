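test_that("anchored interval arithmetic matches the zero-less convention", {
  expect_equal(interval_length(anchored_interval(-2260, -1)), 2260L)
  expect_equal(interval_length(anchored_interval(-2260, 234)), 2494L)
  expect_equal(interval_length(anchored_interval(1, 1)), 1L)
  expect_equal(interval_length(anchored_interval(-1, 1)), 2L)
  expect_error(anchored_interval(0, 5), "coordinate error")
  expect_error(anchored_interval(5, 1), "coordinate error")
  # translation invariance for same-sign intervals
  for (k in c(1, 10, 100)) {
    expect_equal(interval_length(anchored_interval(5 + k, 25 + k)),
                 interval_length(anchored_interval(5, 25)))
  }
  # length(-n, +m) = n + m
  for (n in c(1, 7, 55)) for (m in c(1, 3, 24)) {
    expect_equal(interval_length(anchored_interval(-n, m)), n + m)
  }
})

test_that("reverse complement is an involution and handles the probe", {
  expect_equal(reverse_complement("ACACACAGCTCGATCTACAGGGTA"),
               "TACCCTGTAGATCGAGCTGTGTGT")
  expect_equal(reverse_complement("A"), "T")
  expect_equal(reverse_complement("GAATTC"), "GAATTC")  # palindrome
  expect_equal(reverse_complement("acGT"), "ACgt")      # case preserved
  expect_error(reverse_complement("AXC"), "alphabet error")
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N"), 30,
                      replace = TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(nchar(reverse_complement(s)), nchar(s))
  }
  # independent cross-check against Biostrings on plain DNA
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
    expect_equal(reverse_complement(s),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(s))))
  }
})

test_that("deletion alleles remove covered features and set the null flag", {
  lf <- mir57_locus_fixture()
  res <- apply_deletion(lf$locus, lf$gk175)
  expect_equal(res$deletion_bp, 414L)
  expect_true(res$null)
  expect_true("stem_loop" %in% res$removed)
  # zero-overlap deletion changes nothing
  tiny <- deletion_allele("toy", -2200, -2100)
  res2 <- apply_deletion(lf$locus, tiny)
  expect_false(res2$null)
  expect_equal(nrow(res2$annotation$features), nrow(lf$locus$features))
  # covering only half the stem-loop leaves the gene non-null, with warning
  half <- deletion_allele("half", -30, 10)
  expect_warning(res3 <- apply_deletion(lf$locus, half), "partially")
  expect_false(res3$null)
  # deletion outside the locus span errors
  expect_error(apply_deletion(lf$locus, deletion_allele("far", -9000, -8000)),
               "range error")
})

brute_seed_scan <- function(mirna, utr) {
  # independent oracle: character-level scan
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  m <- strsplit(toupper(chartr("U", "T", mirna)), "")[[1]]
  u <- strsplit(toupper(utr), "")[[1]]
  rc <- function(x) rev(unname(comp[x]))
  core <- paste(rc(m[2:7]), collapse = "")
  hits <- list()
  for (i in seq_len(length(u) - 5)) {
    if (paste(u[i:(i + 5)], collapse = "") != core) next
    m8 <- i > 1 && u[i - 1] == comp[[m[8]]]
    a1 <- i + 6 <= length(u) && u[i + 6] == "A"
    cls <- if (m8 && a1) "8mer" else if (m8) "7mer-m8" else
      if (a1) "7mer-A1" else "6mer"
    hits[[length(hits) + 1L]] <- c(if (m8) i - 1 else i,
                                   if (a1) i + 6 else i + 5, cls)
  }
  hits
}

test_that("seed-match scanning agrees exactly with a brute-force oracle", {
  set.seed(7)
  mirna <- "UACCCUGUAGAUCGAGCUGUGUGU"
  for (rep in 1:100) {
    utr <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                 collapse = "")
    got <- find_seed_matches(mirna, utr)
    want <- brute_seed_scan(mirna, utr)
    expect_equal(nrow(got), length(want))
    if (nrow(got)) {
      expect_equal(got$start, as.integer(vapply(want, `[`, "", 1)))
      expect_equal(got$end, as.integer(vapply(want, `[`, "", 2)))
      expect_equal(got$class, vapply(want, `[`, "", 3))
      expect_true(verify_seed_matches(got, mirna, utr))
    }
  }
})

test_that("constructed seed sites get their canonical class", {
  m <- "UACCCUGUAGAUCGAGCUGUGUGU"
  rc8 <- reverse_complement(chartr("U", "T", substr(m, 1, 8)))
  utr8 <- paste0("GGGG", rc8, "TTTT")   # A opposite position 1 (m1 = U)
  got <- find_seed_matches(m, utr8)
  expect_equal(got$class, "8mer")
  expect_equal(c(got$start, got$end), c(5L, 12L))
  expect_equal(nrow(find_seed_matches(m, "GGGGGGGGGGGG")), 0L)
})

test_that("motif scanning expands IUPAC codes and matches an oracle", {
  expect_setequal(scan_motif("ATGGGAAGTGGGAACTGGGAA", "RTGGGAA")$start,
                  c(1L, 8L))                     # R = A or G only
  expect_error(scan_motif("ACGT", "RJQ"), "IUPAC")
  set.seed(99)
  brute <- function(s, cons) {
    expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
    sv <- strsplit(s, "")[[1]]; cv <- strsplit(cons, "")[[1]]
    out <- integer(0)
    for (i in seq_len(length(sv) - length(cv) + 1)) {
      okk <- TRUE
      for (k in seq_along(cv)) {
        if (!grepl(sv[i + k - 1], expand[[cv[k]]], fixed = TRUE)) {
          okk <- FALSE; break
        }
      }
      if (okk) out <- c(out, i)
    }
    out
  }
  for (rep in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    cons <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N", "W"), 6,
                         replace = TRUE), collapse = "")
    got <- scan_motif(s, cons)
    expect_equal(got$start, brute(s, cons))
  }
})

test_that("both-strand scanning reports reverse hits on forward coordinates", {
  s <- paste0("TTTT", reverse_complement("ATGGGAA"), "TTTT")
  hits <- scan_motif(s, "RTGGGAA", both_strands = TRUE)
  expect_equal(hits$strand, "-")
  expect_equal(c(hits$start, hits$end), c(5L, 11L))
})

test_that("the packaged locus places the CSL site 55 bp upstream", {
  lf <- mir57_locus_fixture()
  hits <- scan_motif(lf$sequence, lf$lag1_consensus, anchor = lf$anchor)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$upstream_bp, 55L)
  expect_equal(hits$anch_start, -61L)
  expect_equal(hits$anch_end, -55L)
  # the planted mature sequence sits at anchored +1..+24
  expect_equal(substr(lf$sequence, lf$anchor, lf$anchor + 23), lf$mature)
})

test_that("FASTA round-trips through Biostrings wrappers", {
  path <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(a = "ACGTACGT", b = "GGGCCC")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})
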