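#' @title Expression calling on lineage trees
#' @description Converts per-nucleus channel intensities into per-cell time
#'   series, removes the per-embryo background ("blot" subtraction) so that
#'   marginally expressing cells are not called, detects expression onset
#'   and the live-cell-count stage at onset, and summarizes the expressing
#'   sublineages as a minimal set of subtree roots.
#' @name expression
NULL

#' Extract per-cell intensity series from a tracked tree
#'
#' @param tree `tracked_tree` with named or unnamed cells.
#' @param channel "red" or "green".
#' @return a `cell_series_set`: data.frame with columns `cell` (name if
#'   assigned, else the cell id as character), `cell_id`, `time`, `raw`
#'   and `corrected` (NA until [background_subtract()] is applied).
#' @export
extract_series <- function(tree, channel = c("red", "green")) {
  channel <- match.arg(channel)
  rec <- tree$records
  if (!nrow(rec)) {
    out <- data.frame(cell = character(0), cell_id = integer(0),
                      time = numeric(0), raw = numeric(0),
                      corrected = numeric(0))
    class(out) <- c("cell_series_set", "data.frame")
    return(out)
  }
  nm <- tree$cells$name[match(rec$cell_id, tree$cells$cell_id)]
  nm[is.na(nm)] <- as.character(rec$cell_id[is.na(nm)])
  out <- data.frame(cell = nm, cell_id = rec$cell_id, time = rec$time,
                    raw = rec[[channel]], corrected = NA_real_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_id, out$time), ]
  rownames(out) <- NULL
  class(out) <- c("cell_series_set", "data.frame")
  out
}

#' Background ("blot") subtraction
#'
#' Estimates the per-embryo background separately at every timepoint from
#' the lowest-intensity half of the live cells and subtracts
#' mean + k * SD, flooring at zero:
#' `corrected = max(0, raw - (bg_mean + k * bg_sd))`. This removes
#' marginally expressing cells so that only robust expression is called.
#' Because the lowest half of a Gaussian background underestimates both its
#' mean and SD, the half-sample moments are rescaled by the half-normal
#' constants (SD by 1/0.6028, mean by +0.7979 SD) so that `bg_mean` and
#' `bg_sd` estimate the full background distribution.
#'
#' @param series `cell_series_set` from [extract_series()].
#' @param k threshold multiplier on the background SD (default 2).
#' @param min_cells timepoints with fewer live cells than this cannot
#'   support a background estimate (the "lowest half" would be one or two
#'   cells); their corrected values are set to zero. Default 10.
#' @return the series set with `corrected` filled in; the per-timepoint
#'   background estimate is attached as `attr(, "background")` (data.frame
#'   `time`, `bg_mean`, `bg_sd`, `threshold`).
#' @export
background_subtract <- function(series, k = 2, min_cells = 10L) {
  n_cells <- length(unique(series$cell_id))
  if (n_cells < 10L) {
    stop("insufficient data: background estimation needs at least 10 cells ",
         "(got ", n_cells, ")", call. = FALSE)
  }
  bg <- do.call(rbind, lapply(split(series$raw, series$time), function(v) {
    if (length(v) < min_cells) {
      # too few live cells to separate signal from background
      return(data.frame(bg_mean = NA_real_, bg_sd = NA_real_,
                        threshold = Inf))
    }
    v <- sort(v)
    half <- v[seq_len(ceiling(length(v) / 2))]
    s_half <- if (length(half) > 1) stats::sd(half) else 0
    s <- s_half / 0.6028                 # half-normal SD correction
    m <- mean(half) + 0.7979 * s         # and mean correction
    data.frame(bg_mean = m, bg_sd = s, threshold = m + k * s)
  }))
  bg$time <- as.numeric(rownames(bg))
  rownames(bg) <- NULL
  thr <- bg$threshold[match(series$time, bg$time)]
  series$corrected <- pmax(0, series$raw - thr)
  attr(series, "background") <- bg[, c("time", "bg_mean", "bg_sd", "threshold")]
  series
}

#' Call expressing cells and their onset
#'
#' A cell is called expressing iff its corrected intensity is positive for
#' at least `min_run` consecutive timepoints; the onset is the first
#' timepoint of the first qualifying run, and the onset stage is the
#' live-cell count at that time (via `stage_fun`).
#'
#' @param series `cell_series_set` with corrected values (see
#'   [background_subtract()]).
#' @param min_run minimum consecutive positive timepoints (default 5).
#' @param stage_fun optional function mapping a timepoint to a live-cell
#'   count, e.g. `function(t) stage_at(canonical_lineage(), t)`; when
#'   `NULL` the onset stage is `NA`.
#' @return an `expression_calls` data.frame: `cell`, `cell_id`,
#'   `expressing`, `onset_tp`, `onset_stage`.
#' @export
call_expression <- function(series, min_run = 5, stage_fun = NULL) {
  if (anyNA(series$corrected)) {
    stop("corrected values missing: run background_subtract() first",
         call. = FALSE)
  }
  per_cell <- lapply(split(seq_len(nrow(series)), series$cell_id), function(ix) {
    ix <- ix[order(series$time[ix])]
    pos <- series$corrected[ix] > 0
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_run)
    if (length(hit)) {
      onset <- series$time[ix[starts[hit[1]]]]
      data.frame(cell = series$cell[ix[1]], cell_id = series$cell_id[ix[1]],
                 expressing = TRUE, onset_tp = onset,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cell = series$cell[ix[1]], cell_id = series$cell_id[ix[1]],
                 expressing = FALSE, onset_tp = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  calls <- do.call(rbind, per_cell)
  rownames(calls) <- NULL
  calls$onset_stage <- NA_integer_
  if (!is.null(stage_fun)) {
    i <- which(calls$expressing)
    calls$onset_stage[i] <- vapply(calls$onset_tp[i],
                                   function(t) as.integer(stage_fun(t)),
                                   integer(1))
  }
  class(calls) <- c("expression_calls", "data.frame")
  calls
}

#' Stage function for a tracked tree
#'
#' Live-cell count of the tree itself at a timepoint (cells whose record
#' span covers the timepoint).
#'
#' @param tree `tracked_tree`.
#' @return function(timepoint) -> integer count.
#' @export
stage_fun_tree <- function(tree) {
  function(t) nrow(tree_cells_at(tree, t))
}

#' Warn about broken bilateral symmetry in expression calls
#'
#' The wild-type pattern is bilaterally symmetric; a called cell whose
#' left/right partner exists in the calls but is not called suggests a
#' tracing or thresholding problem.
#'
#' @param calls `expression_calls`.
#' @return character vector of asymmetric cell names (invisibly); each one
#'   is also reported as a warning.
#' @export
check_bilateral_symmetry <- function(calls) {
  named <- calls[!is.na(calls$cell) & calls$cell != "", ]
  asym <- character(0)
  for (i in which(named$expressing)) {
    p <- tryCatch(bilateral_partner(named$cell[i]), error = function(e) NA)
    if (is.na(p) || p == named$cell[i]) next
    j <- match(p, named$cell)
    if (!is.na(j) && !named$expressing[j]) asym <- c(asym, named$cell[i])
  }
  if (length(asym)) {
    warning("bilaterally asymmetric expression calls: ",
            paste(asym, collapse = ", "), call. = FALSE)
  }
  invisible(asym)
}

#' Summarize expressing sublineages
#'
#' Returns the highest (closest-to-root) subtree roots whose terminal
#' (leaf) cells are predominantly expressing: the fraction of expressing
#' leaves under the root must be at least `purity`. Expressing cells not
#' covered by any qualifying subtree are reported singly.
#'
#' @param calls `expression_calls` covering all cells of the tree.
#' @param tree `tracked_tree` the calls were made on.
#' @param purity minimum expressing fraction among a root's leaves,
#'   in (0, 1] (default 0.8).
#' @return list with class `sublineage_summary`: `roots` (character),
#'   `singletons` (expressing cells outside any qualifying subtree) and
#'   `purity`.
#' @export
summarize_sublineages <- function(calls, tree, purity = 0.8) {
  if (!is.numeric(purity) || purity <= 0 || purity > 1) {
    stop("purity must be in (0, 1]", call. = FALSE)
  }
  cells <- tree$cells
  if (!all(cells$cell_id %in% calls$cell_id)) {
    stop("calls must cover all cells of the tree", call. = FALSE)
  }
  is_leaf <- !(cells$cell_id %in% cells$parent_id[!is.na(cells$parent_id)])
  kids_of <- split(cells$cell_id, factor(cells$parent_id,
                                         levels = cells$cell_id))
  expr <- stats::setNames(calls$expressing, calls$cell_id)

  # leaf counts per subtree, bottom-up
  n_leaves <- stats::setNames(integer(nrow(cells)), cells$cell_id)
  n_expr_leaves <- n_leaves
  ord <- order(cells$birth_tp, decreasing = TRUE)  # children before parents
  for (i in ord) {
    cid <- as.character(cells$cell_id[i])
    if (is_leaf[i]) {
      n_leaves[cid] <- 1L
      n_expr_leaves[cid] <- as.integer(isTRUE(expr[cid]))
    } else {
      kc <- as.character(kids_of[[cid]])
      n_leaves[cid] <- sum(n_leaves[kc])
      n_expr_leaves[cid] <- sum(n_expr_leaves[kc])
    }
  }
  qualifies <- n_leaves > 0 & (n_expr_leaves / pmax(n_leaves, 1L)) >= purity

  parent_of <- stats::setNames(cells$parent_id, cells$cell_id)
  highest_root <- function(cid) {
    best <- NA_character_
    cur <- cid
    while (!is.na(cur)) {
      if (qualifies[as.character(cur)]) best <- as.character(cur)
      cur <- parent_of[as.character(cur)]
    }
    best
  }
  expressing_ids <- calls$cell_id[calls$expressing]
  expressing_ids <- expressing_ids[expressing_ids %in% cells$cell_id]
  roots_id <- unique(stats::na.omit(vapply(expressing_ids, highest_root,
                                           character(1))))
  covered <- function(cid) {
    cur <- cid
    while (!is.na(cur)) {
      if (as.character(cur) %in% roots_id) return(TRUE)
      cur <- parent_of[as.character(cur)]
    }
    FALSE
  }
  singles <- expressing_ids[!vapply(expressing_ids, covered, logical(1))]
  name_of <- function(ids) {
    nm <- cells$name[match(as.integer(ids), cells$cell_id)]
    ifelse(is.na(nm), as.character(ids), nm)
  }
  structure(list(roots = name_of(roots_id),
                 root_ids = as.integer(roots_id),
                 singletons = name_of(singles),
                 purity = purity),
            class = "sublineage_summary")
}

#' @export
print.sublineage_summary <- function(x, ...) {
  cat("expressing sublineage roots (purity >=", x$purity, "):\n  ",
      paste(sort(x$roots), collapse = ", "), "\n")
  if (length(x$singletons)) {
    cat("singleton expressing cells:\n  ",
        paste(sort(x$singletons), collapse = ", "), "\n")
  }
  invisible(x)
}
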