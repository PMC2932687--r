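#' @title Lineage-fate transformation detection
#' @description Homeotic fate transformations (e.g. MS adopting an E fate
#'   after pop-1 RNAi, or loss of Cxa/Cxp cell-cycle asymmetry) leave a
#'   signature in cell-cycle timing. A subtree of observed division timings
#'   is classified against candidate canonical subtrees by root-mean-square
#'   difference of log cell-cycle lengths over positionally matched cells,
#'   truncated to the shallower tree. Terminal-fate identity is ignored:
#'   only timing is compared.
#' @name fate-classify
NULL

#' Cycle lengths of a subtree, indexed by position
#'
#' Walks the binary subtree under `root` and returns one row per dividing
#' (non-terminal) cell with its positional address relative to the root
#' ("" for the root itself, then "1"/"2" for anterior/left vs
#' posterior/right daughters, "11", "12", ...) and its cell-cycle length.
#' Positional addresses make subtrees comparable across division-axis
#' letters.
#'
#' @param lin a lineage table (`canonical_lineage` or compatible data.frame
#'   with `name`, `birth_min`, `end_min`, `terminal`).
#' @param root root cell name.
#' @param max_depth maximum address length to descend to (root = depth 0).
#' @return data.frame with columns `address`, `name`, `cycle`.
#' @export
subtree_cycle_map <- function(lin, root, max_depth = Inf) {
  i <- match(root, lin$name)
  if (is.na(i)) stop("root '", root, "' not in lineage", call. = FALSE)
  out <- list()
  walk <- function(name, address) {
    j <- match(name, lin$name)
    if (is.na(j) || isTRUE(lin$terminal[j])) return(invisible(NULL))
    out[[length(out) + 1L]] <<- data.frame(
      address = address, name = name,
      cycle = lin$end_min[j] - lin$birth_min[j], stringsAsFactors = FALSE
    )
    if (nchar(address) + 1L > max_depth) return(invisible(NULL))
    d <- daughters_of(name)
    walk(d[1], paste0(address, "1"))
    walk(d[2], paste0(address, "2"))
  }
  walk(root, "")
  if (!length(out)) {
    return(data.frame(address = character(0), name = character(0),
                      cycle = numeric(0)))
  }
  do.call(rbind, out)
}

#' Classify the lineage fate of an observed subtree by division timing
#'
#' Scores each candidate canonical subtree by the root-mean-square
#' difference of log cell-cycle lengths over positionally matched dividing
#' cells, after truncating both trees to the depth of the shallower one,
#' and returns the best (minimum-RMS) candidate.
#'
#' @param observed lineage table holding the observed subtree (timings in
#'   minutes; any naming rooted at `observed_root`).
#' @param observed_root root cell name of the observed subtree.
#' @param candidates character vector of candidate root names in `canonical`.
#' @param canonical canonical lineage (default: the packaged one).
#' @return list with `best` (candidate root name), `score` (its RMS), and
#'   `scores` (named vector over all candidates).
#' @examples
#' lin <- canonical_lineage()
#' classify_subtree_fate(lin, "MS", c("MS", "E"))$best  # "MS"
#' @export
classify_subtree_fate <- function(observed, observed_root, candidates,
                                  canonical = canonical_lineage()) {
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  obs <- subtree_cycle_map(observed, observed_root)
  obs_depth <- if (nrow(obs)) max(nchar(obs$address)) else -1L
  if (obs_depth < 1L) {
    stop("observed subtree must contain at least two generations of ",
         "dividing cells", call. = FALSE)
  }
  scores <- vapply(candidates, function(cand) {
    cm <- subtree_cycle_map(canonical, cand)
    depth <- min(obs_depth, if (nrow(cm)) max(nchar(cm$address)) else -1L)
    a <- obs[nchar(obs$address) <= depth, ]
    b <- cm[nchar(cm$address) <= depth, ]
    m <- merge(a, b, by = "address", suffixes = c(".obs", ".can"))
    if (!nrow(m)) return(Inf)
    sqrt(mean((log(m$cycle.obs) - log(m$cycle.can))^2))
  }, numeric(1))
  best <- names(scores)[which.min(scores)]
  list(best = best, score = unname(scores[best]), scores = scores)
}
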