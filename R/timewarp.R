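#' @title Division-timing normalization and embryo comparison
#' @description Embryos differ in absolute clock rate, so expression
#'   profiles are compared on canonical time: a piecewise-linear warp maps
#'   each embryo's observed minutes onto the canonical lineage's minutes,
#'   anchored at matched division events along every root-to-leaf path.
#'   Expression values are then interpolated onto the canonical 1-minute
#'   grid, averaged across embryos, and compared between conditions with a
#'   per-cell two-sample t test at a chosen canonical minute.
#' @name timewarp
NULL

#' Observed timings of a tracked tree
#'
#' @param tree `tracked_tree` with names assigned.
#' @return data.frame `name`, `birth_min`, `end_min`, `terminal` on the
#'   frame clock (a cell's division time is taken as its last frame + 1,
#'   the birth frame of its daughters).
#' @export
tree_timings <- function(tree) {
  cells <- tree$cells
  has_kids <- cells$cell_id %in% cells$parent_id[!is.na(cells$parent_id)]
  data.frame(name = cells$name,
             birth_min = as.numeric(cells$birth_tp),
             end_min = as.numeric(cells$end_tp + 1L),
             terminal = !has_kids,
             stringsAsFactors = FALSE)
}

#' Fit a warp from observed to canonical time
#'
#' Anchors are placed at every matched division (and at each matched
#' cell's birth); within a cell the map is linear between its birth and
#' division anchors. Cells without a division anchor (terminal cells) are
#' extended from their birth anchor with the global fallback slope, the
#' least-squares slope through the origin over all division anchor pairs.
#'
#' @param obs data.frame of observed timings (`name`, `birth_min`,
#'   `end_min`, `terminal`), e.g. from [tree_timings()].
#' @param canonical canonical lineage.
#' @return a `warp_map`: per-cell anchor table plus `global_slope`.
#' @export
fit_warp <- function(obs, canonical = canonical_lineage()) {
  m <- match(obs$name, canonical$name)
  keep <- !is.na(m) & !is.na(obs$name)
  if (!any(keep)) stop("warp fit error: no cells matched to canonical",
                       call. = FALSE)
  obs <- obs[keep, , drop = FALSE]
  can <- canonical[m[keep], , drop = FALSE]
  obs_term <- if ("terminal" %in% names(obs)) obs$terminal else FALSE
  div_anchor <- !obs_term & !can$terminal
  if (!any(div_anchor)) stop("warp fit error: no matched divisions",
                             call. = FALSE)
  ox <- obs$end_min[div_anchor]; cy <- can$end_min[div_anchor]
  global_slope <- sum(ox * cy) / sum(ox^2)
  slope <- ifelse(div_anchor,
                  (can$end_min - can$birth_min) / (obs$end_min - obs$birth_min),
                  global_slope)
  if (any(slope <= 0)) {
    stop("warp fit error: non-increasing segment (check timings)",
         call. = FALSE)
  }
  cellmap <- data.frame(name = obs$name,
                        t0_obs = obs$birth_min, t1_obs = obs$end_min,
                        t0_can = can$birth_min, t1_can = can$end_min,
                        slope = slope, has_div = div_anchor,
                        stringsAsFactors = FALSE)
  structure(list(cells = cellmap, global_slope = global_slope),
            class = "warp_map")
}

#' Map an observed time to canonical time
#'
#' @param warp `warp_map`.
#' @param cell cell name giving the lineage context.
#' @param t observed time (minutes), within the cell's observed span.
#' @return canonical time in minutes.
#' @export
warp_time <- function(warp, cell, t) {
  i <- match(cell, warp$cells$name)
  if (is.na(i)) stop("cell '", cell, "' not covered by warp", call. = FALSE)
  w <- warp$cells[i, ]
  w$t0_can + w$slope * (t - w$t0_obs)
}

#' Interpolate a cell's expression series onto the canonical grid
#'
#' Observed sample times are mapped through the warp and the corrected
#' intensity is linearly interpolated at canonical integer minutes, with
#' no extrapolation beyond the warped span.
#'
#' @param series `cell_series_set` (corrected values present).
#' @param warp `warp_map` covering the series' cells.
#' @param cells cells to interpolate (default: all named cells in both).
#' @param minutes specific canonical minutes to evaluate; default the full
#'   covered integer-minute span per cell. Requesting minutes outside the
#'   warped span is a range error.
#' @return an `embryo_profile` data.frame: `cell`, `minute`, `value`.
#' @export
interpolate_profile <- function(series, warp, cells = NULL, minutes = NULL) {
  if (anyNA(series$corrected)) {
    stop("corrected values missing: run background_subtract() first",
         call. = FALSE)
  }
  if (is.null(cells)) {
    cells <- intersect(unique(series$cell), warp$cells$name)
  }
  wc <- warp$cells
  out <- lapply(cells, function(cl) {
    ix <- which(series$cell == cl)
    if (!length(ix)) return(NULL)
    tt <- series$time[ix]; vv <- series$corrected[ix]
    ord <- order(tt); tt <- tt[ord]; vv <- vv[ord]
    w <- wc[match(cl, wc$name), ]
    tc <- w$t0_can + w$slope * (tt - w$t0_obs)
    lo <- ceiling(min(tc)); hi <- floor(max(tc))
    grid <- if (is.null(minutes)) {
      if (lo > hi) return(NULL) else seq(lo, hi)
    } else minutes
    if (any(grid < min(tc) - 1e-9 | grid > max(tc) + 1e-9)) {
      stop("range error: requested minutes outside warped span of '",
           cl, "'", call. = FALSE)
    }
    if (length(tt) == 1L) {
      val <- rep(vv, length(grid))
    } else {
      val <- stats::approx(tc, vv, xout = grid, rule = 1)$y
    }
    data.frame(cell = cl, minute = grid, value = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(cell = character(0), minute = numeric(0),
                      value = numeric(0))
  }
  rownames(out) <- NULL
  class(out) <- c("embryo_profile", "data.frame")
  out
}

#' Average warped profiles across embryos
#'
#' @param profiles list of `embryo_profile` data.frames, one per embryo.
#' @param cell cell to average.
#' @return a `normalized_profile` data.frame on the common (intersection)
#'   minute grid: `cell`, `minute`, `mean`, `sd`, `n` (sd = 0 when n = 1).
#' @export
average_embryos <- function(profiles, cell) {
  per <- lapply(profiles, function(p) p[p$cell == cell, , drop = FALSE])
  per <- per[vapply(per, nrow, integer(1)) > 0]
  if (!length(per)) stop("no embryo covers cell '", cell, "'", call. = FALSE)
  grid <- Reduce(intersect, lapply(per, function(p) p$minute))
  if (!length(grid)) {
    stop("no-overlap error: embryo grids are disjoint for '", cell, "'",
         call. = FALSE)
  }
  grid <- sort(grid)
  vals <- vapply(per, function(p) p$value[match(grid, p$minute)],
                 numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- ncol(vals)
  out <- data.frame(cell = cell, minute = grid,
                    mean = rowMeans(vals),
                    sd = if (n > 1) apply(vals, 1, stats::sd) else 0,
                    n = n, stringsAsFactors = FALSE)
  class(out) <- c("normalized_profile", "data.frame")
  out
}

#' Onset lag between two genes in a lineage context
#'
#' Finds, for each gene, the earliest called onset along the queried cell's
#' ancestral path (the cell itself and every ancestor) -- the time the gene
#' first turned on in that lineage -- maps both onsets to canonical time,
#' and expresses the lag in units of the local canonical cell-cycle length:
#' the cycle of the canonical ancestor of the queried cell within whose
#' lifespan the earlier onset falls. Positive when gene A precedes gene B.
#'
#' @param callsA,callsB `expression_calls` for the two genes.
#' @param warpA,warpB `warp_map`s for the two source embryos.
#' @param cell lineage context (cell name).
#' @param canonical canonical lineage.
#' @return list: `lag_cycles`, `lag_min`, `onset_can` (named length-2),
#'   `onset_cells`, `cycle_min`, `cycle_cell`.
#' @export
onset_lag <- function(callsA, callsB, warpA, warpB, cell,
                      canonical = canonical_lineage()) {
  find_onset <- function(calls, warp, gene) {
    best <- NULL
    cur <- cell
    repeat {
      i <- match(cur, calls$cell)
      if (!is.na(i) && isTRUE(calls$expressing[i])) {
        can <- warp_time(warp, cur, calls$onset_tp[i])
        if (is.null(best) || can < best$can) best <- list(cell = cur, can = can)
      }
      if (cur == "P0") break
      cur <- mother_of(cur)
    }
    if (is.null(best)) {
      stop("missing onset: no ", gene, " onset in the ancestry of '", cell,
           "'", call. = FALSE)
    }
    best
  }
  a <- find_onset(callsA, warpA, "gene A")
  b <- find_onset(callsB, warpB, "gene B")
  t_early <- min(a$can, b$can)
  # canonical ancestor of the context cell spanning the earlier onset
  cyc_cell <- NA_character_
  cur <- cell
  repeat {
    i <- match(cur, canonical$name)
    if (!is.na(i) && canonical$birth_min[i] <= t_early &&
        t_early < canonical$end_min[i] && !canonical$terminal[i]) {
      cyc_cell <- cur
      break
    }
    if (cur == "P0") break
    cur <- mother_of(cur)
  }
  if (is.na(cyc_cell)) {
    stop("cannot locate the earlier onset on the canonical ancestry of '",
         cell, "'", call. = FALSE)
  }
  cyc <- canonical_cycle_length(canonical, cyc_cell)
  list(lag_cycles = (b$can - a$can) / cyc,
       lag_min = b$can - a$can,
       onset_can = c(A = a$can, B = b$can),
       onset_cells = c(A = a$cell, B = b$cell),
       cycle_min = cyc, cycle_cell = cyc_cell)
}

#' Compare treated vs control expression at a canonical minute
#'
#' Per-cell two-sample t test (equal-variance two-tailed Student's t by
#' default; Welch and a label-permutation test are available) on the
#' per-embryo interpolated intensities at canonical minute `minute`. Also
#' reports a per-cell onset-delay summary (difference of mean first
#' positive minute). No multiple-testing correction is applied by default;
#' set `p_adjust = TRUE` for Benjamini-Hochberg.
#'
#' @param treated,control lists of `embryo_profile` data.frames (one per
#'   embryo), each group of size >= 2.
#' @param cells cells to test (default: cells covered at `minute` by every
#'   embryo of both groups).
#' @param minute canonical minute of the comparison (default 215).
#' @param method "student" (default), "welch" or "permutation".
#' @param n_perm permutations for `method = "permutation"`.
#' @param p_adjust apply Benjamini-Hochberg across cells.
#' @return data.frame: `cell`, `mean_treated`, `mean_control`,
#'   `mean_diff`, `statistic`, `p` (and `p_adj`), `onset_delay`.
#' @export
compare_conditions <- function(treated, control, cells = NULL, minute = 215,
                               method = c("student", "welch", "permutation"),
                               n_perm = 1000, p_adjust = FALSE) {
  method <- match.arg(method)
  if (length(treated) < 2 || length(control) < 2) {
    stop("insufficient replicates: need at least 2 embryos per group",
         call. = FALSE)
  }
  value_at <- function(p, cl) {
    v <- p$value[p$cell == cl & p$minute == minute]
    if (!length(v)) NA_real_ else v[1]
  }
  if (is.null(cells)) {
    cov_cells <- function(p) unique(p$cell[p$minute == minute])
    cells <- Reduce(intersect, lapply(c(treated, control), cov_cells))
  }
  if (!length(cells)) stop("no cells covered at minute ", minute, call. = FALSE)
  onset_of <- function(p, cl) {
    m <- p$minute[p$cell == cl & p$value > 0]
    if (!length(m)) NA_real_ else min(m)
  }
  rows <- lapply(cells, function(cl) {
    x <- vapply(treated, value_at, numeric(1), cl = cl)
    y <- vapply(control, value_at, numeric(1), cl = cl)
    if (anyNA(x) || anyNA(y)) {
      stop("cell '", cl, "' not covered at minute ", minute,
           " in every embryo", call. = FALSE)
    }
    if (stats::sd(c(x, y)) == 0) {
      stat <- 0; p <- 1
    } else if (method == "permutation") {
      obs <- mean(x) - mean(y)
      pool <- c(x, y); nx <- length(x)
      perm <- vapply(seq_len(n_perm), function(i) {
        s <- sample.int(length(pool), nx)
        mean(pool[s]) - mean(pool[-s])
      }, numeric(1))
      stat <- obs
      p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
    } else {
      tt <- stats::t.test(x, y, var.equal = (method == "student"))
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    od_t <- vapply(treated, onset_of, numeric(1), cl = cl)
    od_c <- vapply(control, onset_of, numeric(1), cl = cl)
    delay <- mean(od_t, na.rm = TRUE) - mean(od_c, na.rm = TRUE)
    data.frame(cell = cl, mean_treated = mean(x), mean_control = mean(y),
               mean_diff = mean(x) - mean(y), statistic = stat, p = p,
               onset_delay = delay, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
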