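#' @title Tracked-nuclei tables and lineage trees
#' @description I/O for the documented nuclei CSV dialect and the
#'   `tracked_tree` container that tracking produces. The dialect is one row
#'   per nucleus per timepoint with header
#'   `time,id,x,y,z,diameter,name,red,green`: 1-based timepoint index at
#'   1-minute sampling, positions and diameter in micrometres in a
#'   right-handed frame with +x pointing anterior to posterior, an optional
#'   assigned cell name, and the two channel intensities in arbitrary units.
#' @name tracking-io
NULL

.nuclei_cols <- c("time", "id", "x", "y", "z", "diameter", "name", "red",
                  "green")

#' Read a tracked-nuclei table
#'
#' Validates the header and every row (numeric coordinates, positive
#' diameter, timepoint >= 1, non-negative intensities); malformed rows are
#' reported with their line numbers. Records are returned sorted by
#' (timepoint, nucleus id).
#'
#' @param path CSV file in the documented dialect.
#' @return data.frame of nucleus records with class `nuclei_table`.
#' @export
read_nuclei_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(name = "character"))
  missing_cols <- setdiff(.nuclei_cols, names(df))
  if (length(missing_cols)) {
    stop("nuclei table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[.nuclei_cols]
  as_nuclei_table(df, source = path)
}

#' Coerce and validate a data.frame of nucleus records
#'
#' @param df data.frame with the documented columns.
#' @param source label used in error messages (file path or "data.frame").
#' @return `nuclei_table`.
#' @export
as_nuclei_table <- function(df, source = "data.frame") {
  for (col in c("time", "id", "x", "y", "z", "diameter", "red", "green")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("nuclei table format error in ", source, ": non-numeric '", col,
           "' at line(s) ", paste(bad + 1L, collapse = ", "), call. = FALSE)
    }
    df[[col]] <- v
  }
  df$name[is.na(df$name)] <- ""
  bad_rows <- which(df$time < 1 | df$diameter <= 0 | df$red < 0 | df$green < 0)
  if (length(bad_rows)) {
    stop("nuclei table format error in ", source, ": invalid record at ",
         "line(s) ", paste(bad_rows + 1L, collapse = ", "),
         " (need time >= 1, diameter > 0, intensities >= 0)", call. = FALSE)
  }
  df <- df[order(df$time, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("nuclei_table", "data.frame")
  df
}

#' @rdname read_nuclei_table
#' @param records `nuclei_table` (or compatible data.frame) to write.
#' @export
write_nuclei_table <- function(records, path) {
  out <- as.data.frame(records)[.nuclei_cols]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linking parameters for nuclei tracking
#'
#' @param max_disp maximum nucleus displacement per frame (um) for
#'   frame-to-frame links.
#' @param max_gap maximum number of frames bridged when a nucleus drops out.
#' @param link_accept distance (um) at which a backward-traced nucleus is
#'   accepted as "reliably linked" to a forward-tracked nucleus at the same
#'   timepoint. The default, half the median inter-nuclear spacing, is
#'   computed from the data when `NULL`.
#' @param division_radius radius (um) within which newly appearing nuclei
#'   are attributed to a dividing mother.
#' @param ambiguity_tol two link candidates closer than this (um) to the
#'   same nucleus are reported as an ambiguity error rather than resolved
#'   silently.
#' @return list with class `link_params`.
#' @export
link_params <- function(max_disp = 5, max_gap = 1, link_accept = NULL,
                        division_radius = 6, ambiguity_tol = 1e-6) {
  stopifnot(max_disp > 0, max_gap > 0, division_radius > 0,
            is.null(link_accept) || link_accept > 0)
  structure(list(max_disp = max_disp, max_gap = max_gap,
                 link_accept = link_accept,
                 division_radius = division_radius,
                 ambiguity_tol = ambiguity_tol),
            class = "link_params")
}

#' Median nearest-neighbour spacing of a nuclei table
#'
#' @param records `nuclei_table`.
#' @return median over frames of the median nearest-neighbour distance.
#' @export
median_spacing <- function(records) {
  per_frame <- vapply(split(seq_len(nrow(records)), records$time),
                      function(ix) {
    if (length(ix) < 2) return(NA_real_)
    p <- as.matrix(records[ix, c("x", "y", "z")])
    d <- as.matrix(stats::dist(p))
    diag(d) <- Inf
    stats::median(apply(d, 1, min))
  }, numeric(1))
  stats::median(per_frame, na.rm = TRUE)
}

.resolve_link_accept <- function(params, records) {
  if (!is.null(params$link_accept)) return(params$link_accept)
  0.5 * median_spacing(records)
}

#' Construct a tracked tree
#'
#' @param cells data.frame with columns `cell_id`, `parent_id`, `name`,
#'   `birth_tp`, `end_tp`.
#' @param records nuclei records with an added `cell_id` column.
#' @return object of class `tracked_tree`.
#' @export
new_tracked_tree <- function(cells, records) {
  structure(list(cells = cells, records = records), class = "tracked_tree")
}

#' @export
print.tracked_tree <- function(x, ...) {
  named <- sum(!is.na(x$cells$name))
  cat("tracked_tree:", nrow(x$cells), "cells (", named, "named ),",
      nrow(x$records), "records, frames",
      min(x$records$time), "-", max(x$records$time), "\n")
  invisible(x)
}

#' Validate tracked-tree invariants
#'
#' Checks that every record belongs to exactly one cell, that records within
#' a cell are consecutive in time (one per timepoint), and that every
#' daughter's birth timepoint is its mother's end timepoint plus one.
#'
#' @param tree `tracked_tree`.
#' @return `tree` invisibly; errors on violation.
#' @export
validate_tracked_tree <- function(tree) {
  cells <- tree$cells; rec <- tree$records
  if (anyNA(rec$cell_id)) stop("record(s) not assigned to any cell", call. = FALSE)
  if (anyDuplicated(rec[c("time", "id")])) {
    stop("duplicate (time, id) records", call. = FALSE)
  }
  for (i in seq_len(nrow(cells))) {
    tps <- sort(rec$time[rec$cell_id == cells$cell_id[i]])
    if (!length(tps)) stop("cell ", cells$cell_id[i], " has no records", call. = FALSE)
    if (anyDuplicated(tps) || any(diff(tps) != 1)) {
      stop("records of cell ", cells$cell_id[i],
           " are not consecutive in time", call. = FALSE)
    }
    if (tps[1] != cells$birth_tp[i] || tps[length(tps)] != cells$end_tp[i]) {
      stop("birth/end of cell ", cells$cell_id[i],
           " do not match its records", call. = FALSE)
    }
    pid <- cells$parent_id[i]
    if (!is.na(pid)) {
      pend <- cells$end_tp[match(pid, cells$cell_id)]
      if (cells$birth_tp[i] != pend + 1L) {
        stop("daughter ", cells$cell_id[i],
             " not born at mother's end + 1", call. = FALSE)
      }
    }
  }
  invisible(tree)
}

#' Serialize / deserialize a tracked tree to the documented JSON schema
#'
#' @param tree `tracked_tree`.
#' @param path output (input) file.
#' @return `path` (`tracked_tree` for the reader).
#' @export
write_tracked_tree <- function(tree, path) {
  jsonlite::write_json(
    list(schema = "lintrex-tree/1",
         cells = tree$cells, records = tree$records),
    path, dataframe = "columns", na = "null", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_tracked_tree
#' @export
read_tracked_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "lintrex-tree/1")) {
    stop("not a lintrex tree JSON file: ", path, call. = FALSE)
  }
  cells <- as.data.frame(obj$cells)
  cells$name <- as.character(cells$name)
  recs <- as.data.frame(obj$records)
  recs$name <- as.character(recs$name)
  new_tracked_tree(cells, recs)
}

#' Cells alive at a timepoint of a tracked tree
#'
#' @param tree `tracked_tree`.
#' @param tp timepoint index.
#' @return data.frame rows of `tree$cells` for cells spanning `tp`.
#' @export
tree_cells_at <- function(tree, tp) {
  tree$cells[tree$cells$birth_tp <= tp & tree$cells$end_tp >= tp, , drop = FALSE]
}

#' Assign Sulston names to a tracked tree by division order
#'
#' Starting from a single named root (default "P0"), daughters at every
#' division receive the names from [daughters_of()], the anterior/left name
#' going to the daughter with the smaller x coordinate at birth (the
#' documented frame has +x anterior to posterior). Ties are broken toward
#' the first daughter with a warning.
#'
#' @param tree `tracked_tree`.
#' @param root_name name for the root cell.
#' @return the tree with `cells$name` (and `records$name`) filled in.
#' @export
assign_tree_names <- function(tree, root_name = "P0") {
  cells <- tree$cells
  roots <- which(is.na(cells$parent_id))
  if (length(roots) != 1L) {
    stop("naming requires a single-root tree (found ", length(roots),
         " roots)", call. = FALSE)
  }
  cells$name <- NA_character_
  cells$name[roots] <- root_name
  birth_x <- function(cid) {
    # mean x over the first few frames: single-frame positions are too
    # noisy to order daughters reliably under realistic jitter
    r <- tree$records
    i <- which(r$cell_id == cid)
    i <- i[order(r$time[i])]
    mean(r$x[utils::head(i, 5L)])
  }
  queue <- roots
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    kids <- which(!is.na(cells$parent_id) &
                    cells$parent_id == cells$cell_id[i])
    if (!length(kids)) next
    if (length(kids) != 2L || is.na(cells$name[i])) {
      queue <- c(queue, kids)  # leave unnameable subtrees NA
      next
    }
    dn <- tryCatch(daughters_of(cells$name[i]), error = function(e) NULL)
    if (is.null(dn)) { queue <- c(queue, kids); next }
    xs <- vapply(cells$cell_id[kids], birth_x, numeric(1))
    if (xs[1] == xs[2]) {
      warning("anterior/posterior tie at division of ", cells$name[i],
              "; assigning first daughter anterior", call. = FALSE)
    }
    ord <- order(xs)
    cells$name[kids[ord]] <- dn
    queue <- c(queue, kids)
  }
  tree$cells <- cells
  tree$records$name <- cells$name[match(tree$records$cell_id, cells$cell_id)]
  tree$records$name[is.na(tree$records$name)] <- ""
  tree
}
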