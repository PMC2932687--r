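#' @title Regulatory-sequence utilities
#' @description Coordinate arithmetic in the mature-miRNA-anchored
#'   convention (mature start = +1, the adjacent upstream base = -1, no
#'   position 0, both ends inclusive), deletion alleles over locus feature
#'   annotations, reverse complement over the full IUPAC alphabet, miRNA
#'   seed-match scanning with the canonical site taxonomy (6mer, 7mer-A1,
#'   7mer-m8, 8mer), and IUPAC consensus motif scanning.
#' @name seq-regulatory
NULL

.iupac_from <- "ACGTURYSWKMBDHVN"
.iupac_to   <- "TGCAAYRSWMKVHDBN"

.iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
                   R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT",
                   M = "AC", B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                   N = "ACGT")

#' Anchored interval (mature-miRNA coordinates)
#'
#' Positions are nonzero integers: +1 is the first base of the mature
#' miRNA, -1 the base immediately upstream; both interval ends are
#' inclusive and ordered ... -2, -1, +1, +2 ...
#'
#' @param start,end nonzero integer positions with `start <= end` in the
#'   zero-less ordering.
#' @return object of class `anchored_interval`.
#' @examples
#' interval_length(anchored_interval(-2260, -1))   # 2260
#' interval_length(anchored_interval(-2260, 234))  # 2494
#' @export
anchored_interval <- function(start, end) {
  for (p in c(start, end)) {
    if (!is.numeric(p) || p != as.integer(p) || p == 0) {
      stop("coordinate error: anchored positions are nonzero integers ",
           "(got ", p, ")", call. = FALSE)
    }
  }
  if (.anch_off(start) > .anch_off(end)) {
    stop("coordinate error: start must not follow end", call. = FALSE)
  }
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "anchored_interval")
}

# map the zero-less axis onto consecutive integers (-1 -> -1, +1 -> 0)
.anch_off <- function(p) {
  p <- as.integer(p)
  ifelse(p > 0L, p - 1L, p)
}

#' @rdname anchored_interval
#' @param iv `anchored_interval`.
#' @export
interval_length <- function(iv) {
  if (!inherits(iv, "anchored_interval")) iv <- anchored_interval(iv[1], iv[2])
  .anch_off(iv$end) - .anch_off(iv$start) + 1L
}

#' @export
print.anchored_interval <- function(x, ...) {
  cat(sprintf("anchored interval (%+d, %+d), %d bp\n", x$start, x$end,
              interval_length(x)))
  invisible(x)
}

#' Locus annotation
#'
#' A locus is a span in anchored coordinates plus a feature table
#' (`feature`, `start`, `end`), e.g. the miRNA stem-loop, the mature
#' sequence, and promoter motifs.
#'
#' @param span `anchored_interval` covered by the locus.
#' @param features data.frame with columns `feature`, `start`, `end`
#'   (anchored coordinates).
#' @return object of class `locus_annotation`.
#' @export
locus_annotation <- function(span, features) {
  stopifnot(all(c("feature", "start", "end") %in% names(features)))
  for (i in seq_len(nrow(features))) {
    anchored_interval(features$start[i], features$end[i])  # validates
  }
  structure(list(span = span, features = features), class = "locus_annotation")
}

#' Deletion allele
#'
#' @param name allele name (e.g. "gk175").
#' @param start,end deleted anchored interval (inclusive).
#' @return object of class `deletion_allele`.
#' @export
deletion_allele <- function(name, start, end) {
  structure(list(name = name, interval = anchored_interval(start, end)),
            class = "deletion_allele")
}

#' Apply a deletion allele to a locus annotation
#'
#' Features fully covered by the deletion are removed; the gene is flagged
#' null iff the stem-loop feature is fully covered. Partial overlap of the
#' stem-loop leaves the null flag unset with a warning.
#'
#' @param locus `locus_annotation`.
#' @param allele `deletion_allele`; must lie within the locus span.
#' @param stem_loop_feature name of the feature whose complete removal
#'   defines a null allele (default "stem_loop").
#' @return list: `annotation` (features surviving), `null` (flag),
#'   `deletion_bp` (length of the deleted interval), `removed` (feature
#'   names removed).
#' @export
apply_deletion <- function(locus, allele, stem_loop_feature = "stem_loop") {
  dl <- allele$interval
  sp <- locus$span
  if (.anch_off(dl$start) < .anch_off(sp$start) ||
      .anch_off(dl$end) > .anch_off(sp$end)) {
    stop("range error: deletion ", allele$name, " lies outside the locus span",
         call. = FALSE)
  }
  f <- locus$features
  off_s <- .anch_off(f$start); off_e <- .anch_off(f$end)
  d_s <- .anch_off(dl$start); d_e <- .anch_off(dl$end)
  covered <- off_s >= d_s & off_e <= d_e
  partial <- !covered & off_e >= d_s & off_s <= d_e
  null_flag <- any(covered & f$feature == stem_loop_feature)
  if (any(partial & f$feature == stem_loop_feature)) {
    warning("deletion ", allele$name, " only partially overlaps the ",
            stem_loop_feature, " feature; gene not flagged null",
            call. = FALSE)
  }
  list(annotation = locus_annotation(sp, f[!covered, , drop = FALSE]),
       null = null_flag,
       deletion_bp = interval_length(dl),
       removed = f$feature[covered])
}

.check_alphabet <- function(seq, what = "sequence") {
  ok <- strsplit(paste0(.iupac_from, tolower(.iupac_from)), "")[[1]]
  ch <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(ch), ok)
  if (length(bad)) {
    stop("alphabet error: illegal character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement
#'
#' Base-wise complement over the full IUPAC alphabet (T and U both
#' complement to A, so mixed DNA/RNA input is accepted), reversed; case is
#' preserved.
#'
#' @param seq DNA/RNA string.
#' @return reverse-complemented string.
#' @examples
#' reverse_complement("ACACACAGCTCGATCTACAGGGTA")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .check_alphabet(seq)
  comp <- chartr(paste0(.iupac_from, tolower(.iupac_from)),
                 paste0(.iupac_to, tolower(.iupac_to)), seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

.complement1 <- function(base) {
  chartr(paste0(.iupac_from, tolower(.iupac_from)),
         paste0(.iupac_to, tolower(.iupac_to)), base)
}

#' Scan a 3' UTR for miRNA seed-match sites
#'
#' Finds every position where the UTR contains the reverse complement of
#' miRNA seed positions 2-7 (6mer core), and classifies each site by the
#' canonical taxonomy: extension of the pairing to position 8 (7mer-m8),
#' an adenosine opposite position 1 (7mer-A1), or both (8mer). Each site
#' is reported once with its best (most extended) class.
#'
#' @param mirna mature miRNA sequence, 5' to 3' (RNA or DNA letters),
#'   length >= 8.
#' @param utr UTR sequence, 5' to 3' (DNA letters).
#' @return data.frame of class `seed_matches`: `mirna_id`, `start`, `end`
#'   (1-based inclusive UTR positions of the reported site), `class`,
#'   `site_seq`.
#' @param mirna_id label used in the output.
#' @export
find_seed_matches <- function(mirna, utr, mirna_id = "miRNA") {
  stopifnot(nchar(mirna) >= 8)
  .check_alphabet(mirna, "miRNA"); .check_alphabet(utr, "UTR")
  m <- toupper(chartr("U", "T", mirna))
  u <- toupper(chartr("U", "T", utr))
  core <- reverse_complement(substr(m, 2, 7))     # pairs positions 7..2
  m8c <- .complement1(substr(m, 8, 8))            # base pairing position 8
  L <- nchar(u)
  hits <- list()
  if (nchar(core) <= L) {
    starts <- c()
    at <- 1L
    repeat {
      i <- regexpr(core, substr(u, at, L), fixed = TRUE)
      if (i == -1L) break
      starts <- c(starts, at + i - 1L)
      at <- at + i
      if (at > L) break
    }
    for (i in starts) {
      has_m8 <- i > 1L && substr(u, i - 1L, i - 1L) == m8c
      has_a1 <- i + 6L <= L && substr(u, i + 6L, i + 6L) == "A"
      cls <- if (has_m8 && has_a1) "8mer"
      else if (has_m8) "7mer-m8"
      else if (has_a1) "7mer-A1"
      else "6mer"
      s <- if (has_m8) i - 1L else i
      e <- if (has_a1) i + 6L else i + 5L
      hits[[length(hits) + 1L]] <- data.frame(
        mirna_id = mirna_id, start = s, end = e, class = cls,
        site_seq = substr(utr, s, e), stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(mirna_id = character(0), start = integer(0), end = integer(0),
               class = character(0), site_seq = character(0))
  class(out) <- c("seed_matches", "data.frame")
  out
}

#' Re-verify a seed-match table against its defining invariant
#'
#' Independently checks, for every reported site, that the UTR subsequence
#' is the reverse complement of the miRNA seed region implied by the
#' stated class (with an A, not the position-1 complement, at the A1 slot).
#'
#' @param matches `seed_matches`.
#' @param mirna,utr the sequences that were scanned.
#' @return `TRUE` (errors on any violation).
#' @export
verify_seed_matches <- function(matches, mirna, utr) {
  m <- toupper(chartr("U", "T", mirna))
  u <- toupper(chartr("U", "T", utr))
  for (i in seq_len(nrow(matches))) {
    cls <- matches$class[i]
    s <- matches$start[i]; e <- matches$end[i]
    site <- substr(u, s, e)
    core_rc <- reverse_complement(substr(m, 2, 7))
    expected <- switch(cls,
      "6mer" = core_rc,
      "7mer-m8" = paste0(.complement1(substr(m, 8, 8)), core_rc),
      "7mer-A1" = paste0(core_rc, "A"),
      "8mer" = paste0(.complement1(substr(m, 8, 8)), core_rc, "A"),
      stop("unknown site class: ", cls, call. = FALSE))
    if (!identical(site, expected)) {
      stop("seed-match invariant violated at ", s, "-", e, ": site '", site,
           "' != expected '", expected, "' for class ", cls, call. = FALSE)
    }
  }
  TRUE
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Degenerate codes in the consensus are expanded; the subject is taken
#' literally. Matching uses Biostrings. When an `anchor` (the 1-based
#' subject position corresponding to anchored position +1) is supplied,
#' hits are also reported in anchored coordinates and with their upstream
#' distance (bp from the hit's downstream edge to position +1).
#'
#' @param seq subject DNA string.
#' @param consensus IUPAC consensus (e.g. "RTGGGAA").
#' @param both_strands also scan the reverse strand (hit coordinates stay
#'   on the forward sequence).
#' @param anchor optional 1-based subject position of anchored +1.
#' @param motif_id label for the output.
#' @return data.frame of class `motif_hits`: `motif_id`, `strand`,
#'   `start`, `end`, `match_seq`, and with an anchor also
#'   `anch_start`, `anch_end`, `upstream_bp`.
#' @export
scan_motif <- function(seq, consensus, both_strands = FALSE, anchor = NULL,
                       motif_id = consensus) {
  if (!nzchar(consensus)) stop("consensus must be nonempty", call. = FALSE)
  bad <- setdiff(strsplit(toupper(consensus), "")[[1]], names(.iupac_expand))
  if (length(bad)) {
    stop("illegal IUPAC code(s) in consensus: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  .check_alphabet(seq)
  subject <- Biostrings::DNAString(toupper(seq))
  one_strand <- function(pat, strand) {
    mp <- Biostrings::matchPattern(Biostrings::DNAString(toupper(pat)),
                                   subject, fixed = "subject")
    if (!length(mp)) return(NULL)
    data.frame(motif_id = motif_id, strand = strand,
               start = Biostrings::start(mp), end = Biostrings::end(mp),
               match_seq = substr(seq, Biostrings::start(mp),
                                  Biostrings::end(mp)),
               stringsAsFactors = FALSE)
  }
  out <- one_strand(consensus, "+")
  if (both_strands) {
    out <- rbind(out, one_strand(reverse_complement(consensus), "-"))
  }
  if (is.null(out)) {
    out <- data.frame(motif_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      match_seq = character(0))
  }
  if (!is.null(anchor) && nrow(out)) {
    anchor <- as.integer(anchor)
    to_anch <- function(p) ifelse(p >= anchor, p - anchor + 1L, p - anchor)
    out$anch_start <- to_anch(out$start)
    out$anch_end <- to_anch(out$end)
    out$upstream_bp <- ifelse(out$anch_end < 0, -out$anch_end, 0L)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
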