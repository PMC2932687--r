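#' @title Phenotype penetrance and bench quantification statistics
#' @description Penetrance tables and their comparison, male tail-ray
#'   summaries, delta-delta-Ct qPCR fold changes normalized to a reference
#'   gene, loading-control-normalized band ratios, and mean-intensity
#'   quantification of a polygonal region of interest. Display rounding is
#'   one decimal, as phenotype tables are conventionally printed; full
#'   precision is kept internally.
#' @name pheno-quant
NULL

#' Penetrance of a phenotype
#'
#' @param records data.frame with one row per animal per assay: columns
#'   `genotype`, `condition`, plus logical phenotype flag columns (e.g.
#'   `Emb`, `Lva`, `Ste`, `Vab`, `Nob`).
#' @param genotype,condition selection values.
#' @param phenotype name of the flag column to score.
#' @return list: `percent` (to one decimal), `percent_raw`, `affected`,
#'   `n`.
#' @export
penetrance <- function(records, genotype, condition, phenotype) {
  sel <- records$genotype == genotype & records$condition == condition
  # tables scoring different animal cohorts per phenotype carry an `assay`
  # column naming the cohort's phenotype
  if (!is.null(records$assay)) sel <- sel & records$assay == phenotype
  if (!any(sel)) {
    stop("empty selection: no records for genotype '", genotype,
         "' at condition '", condition, "'", call. = FALSE)
  }
  flags <- records[[phenotype]][sel]
  if (is.null(flags)) stop("no phenotype column '", phenotype, "'", call. = FALSE)
  n <- sum(sel)
  affected <- sum(flags)
  pct <- 100 * affected / n
  list(percent = round(pct, 1), percent_raw = pct, affected = affected, n = n)
}

#' Compare penetrance between two groups
#'
#' Default is a two-proportion chi-square test on pooled counts (with
#' continuity correction; degenerate zero-count cases are handled by
#' `prop.test`'s correction and logged). A plate-level Student's t test on
#' per-plate percentages is available where a `plate` column exists, to
#' mirror the convention of testing per-plate replicate percentages.
#'
#' @param groupA,groupB data.frames of phenotype records (already
#'   subsetted to the two groups being compared).
#' @param phenotype flag column to score.
#' @param method "two-proportion" (default) or "t-on-plates".
#' @return list: `statistic`, `p`, `estimate` (per-group proportions or
#'   plate means), `method`.
#' @export
compare_penetrance <- function(groupA, groupB, phenotype,
                               method = c("two-proportion", "t-on-plates")) {
  method <- match.arg(method)
  if (!nrow(groupA) || !nrow(groupB)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  a <- groupA[[phenotype]]; b <- groupB[[phenotype]]
  if (method == "two-proportion") {
    x <- c(sum(a), sum(b)); n <- c(length(a), length(b))
    if (x[1] / n[1] == x[2] / n[2]) {
      # identical proportions: p = 1 by convention (prop.test agrees but
      # warns on degenerate zero-count tables)
      return(list(statistic = 0, p = 1, estimate = x / n, method = method))
    }
    if (any(x == 0) || any(x == n)) {
      message("zero-count cell; using continuity-corrected two-proportion test")
    }
    pt <- suppressWarnings(stats::prop.test(x, n, correct = TRUE))
    list(statistic = unname(pt$statistic), p = pt$p.value, estimate = x / n,
         method = method)
  } else {
    if (is.null(groupA$plate) || is.null(groupB$plate)) {
      stop("t-on-plates needs a 'plate' column in both groups", call. = FALSE)
    }
    pa <- tapply(a, groupA$plate, function(v) 100 * mean(v))
    pb <- tapply(b, groupB$plate, function(v) 100 * mean(v))
    if (length(pa) < 2 || length(pb) < 2) {
      stop("t-on-plates needs at least two plates per group", call. = FALSE)
    }
    if (stats::sd(c(pa, pb)) == 0) {
      return(list(statistic = 0, p = 1,
                  estimate = c(mean(pa), mean(pb)), method = method))
    }
    tt <- stats::t.test(pa, pb, var.equal = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         estimate = c(mean(pa), mean(pb)), method = method)
  }
}

#' Delta-delta-Ct relative fold change
#'
#' Per replicate, delta-Ct = Ct(target) - Ct(reference); the fold change of
#' `group` relative to `baseline` is `2 ^ (mean dCt_baseline - mean
#' dCt_group)`, i.e. amplification efficiency is fixed at 2 (kit-default
#' analysis, no standard-curve correction). A bootstrap CI over replicates
#' is attached.
#'
#' @param cts data.frame with columns `group`, `gene`, `replicate`, `ct`.
#' @param target,reference gene names; the reference (e.g. a GAPDH gene
#'   such as gpd-1) must be measured in both groups.
#' @param group,baseline group labels to compare.
#' @param n_boot bootstrap draws (default 1000).
#' @param conf CI level.
#' @return list: `fold`, `ci` (length-2), `dct_group`, `dct_baseline`.
#' @export
ddct_fold_change <- function(cts, target, reference, group, baseline,
                             n_boot = 1000, conf = 0.95) {
  get_ct <- function(g, gene) {
    v <- cts$ct[cts$group == g & cts$gene == gene]
    v[order(cts$replicate[cts$group == g & cts$gene == gene])]
  }
  for (g in c(group, baseline)) {
    if (!length(get_ct(g, reference))) {
      stop("reference gene '", reference, "' not measured in group '", g,
           "'", call. = FALSE)
    }
    if (!length(get_ct(g, target))) {
      stop("target gene '", target, "' not measured in group '", g, "'",
           call. = FALSE)
    }
  }
  dct <- function(g) {
    tg <- get_ct(g, target); rf <- get_ct(g, reference)
    if (length(tg) == length(rf)) tg - rf else tg - mean(rf)
  }
  dg <- dct(group); db <- dct(baseline)
  fold <- 2^(mean(db) - mean(dg))
  boots <- vapply(seq_len(n_boot), function(i) {
    2^(mean(sample(db, replace = TRUE)) - mean(sample(dg, replace = TRUE)))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(fold = fold,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       dct_group = dg, dct_baseline = db)
}

#' Loading-control-normalized band ratios
#'
#' @param signal numeric vector of band intensities (one per lane).
#' @param control loading-control intensities (same lanes, all > 0).
#' @param reference_lane index of the lane folds are expressed against.
#' @return data.frame: `lane`, `level` (signal/control), `fold`
#'   (level / reference level).
#' @export
normalized_band_ratio <- function(signal, control, reference_lane = 1L) {
  if (length(signal) != length(control)) {
    stop("signal and loading-control lanes must match", call. = FALSE)
  }
  if (any(control <= 0)) {
    stop("division error: loading control must be positive in every lane",
         call. = FALSE)
  }
  level <- signal / control
  data.frame(lane = seq_along(signal), level = level,
             fold = level / level[reference_lane])
}

#' Summarize male tail-ray counts
#'
#' @param counts nonnegative integer ray counts (one tail side per animal).
#' @return list: `mean`, `sd` (both to one decimal), `n`, and a formatted
#'   `label` like "8.6±1.2 (n = 57)".
#' @export
summarize_rays <- function(counts) {
  if (!length(counts)) stop("empty selection: no ray counts", call. = FALSE)
  if (any(counts < 0) || any(counts != as.integer(counts))) {
    stop("ray counts must be nonnegative integers", call. = FALSE)
  }
  m <- mean(counts)
  s <- if (length(counts) > 1) stats::sd(counts) else 0
  list(mean = round(m, 1), sd = round(s, 1), n = length(counts),
       label = sprintf("%.1f±%.1f (n = %d)", round(m, 1), round(s, 1),
                       length(counts)))
}

#' Mean intensity inside a polygonal region of interest
#'
#' Pixels whose centres fall inside the polygon (even-odd crossing rule;
#' boundary pixels count as inside) are averaged. Used for tail-region
#' reporter quantification; [roi_group_summary()] gives the box-plot
#' statistics per line.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param roi two-column matrix of polygon vertices (x, y) in pixel
#'   coordinates.
#' @return mean pixel intensity inside the ROI.
#' @export
roi_intensity <- function(image, roi) {
  roi <- as.matrix(roi)
  if (ncol(roi) != 2 || nrow(roi) < 3) {
    stop("ROI must be a polygon with >= 3 (x, y) vertices", call. = FALSE)
  }
  if (any(roi[, 1] < 1) || any(roi[, 1] > ncol(image)) ||
      any(roi[, 2] < 1) || any(roi[, 2] > nrow(image))) {
    stop("ROI outside image bounds", call. = FALSE)
  }
  xs <- seq_len(ncol(image)); ys <- seq_len(nrow(image))
  inside <- matrix(FALSE, nrow(image), ncol(image))
  vx <- roi[, 1]; vy <- roi[, 2]; nv <- nrow(roi)
  for (yy in ys) {
    # even-odd crossing test along the horizontal line y = yy
    cross <- numeric(0)
    for (k in seq_len(nv)) {
      j <- if (k == nv) 1L else k + 1L
      y1 <- vy[k]; y2 <- vy[j]
      if ((y1 <= yy && y2 > yy) || (y2 <= yy && y1 > yy)) {
        cross <- c(cross, vx[k] + (yy - y1) / (y2 - y1) * (vx[j] - vx[k]))
      }
    }
    if (!length(cross)) next
    cross <- sort(cross)
    for (q in seq(1, length(cross) - 1, by = 2)) {
      inside[yy, xs >= cross[q] & xs <= cross[q + 1]] <- TRUE
    }
  }
  if (!any(inside)) stop("empty ROI: no pixels inside polygon", call. = FALSE)
  mean(image[inside])
}

#' Box-plot summary of ROI intensities per line
#'
#' @param measurements data.frame with columns `line` and `intensity`.
#' @return data.frame per line: `n`, `median`, `q1`, `q3`, `mean`.
#' @export
roi_group_summary <- function(measurements) {
  out <- do.call(rbind, lapply(split(measurements$intensity,
                                     measurements$line), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               mean = mean(v))
  }))
  out$line <- rownames(out)
  rownames(out) <- NULL
  out[, c("line", "n", "median", "q1", "q3", "mean")]
}
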