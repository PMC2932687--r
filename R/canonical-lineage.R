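#' @title Canonical lineage model
#' @description A reference binary lineage with per-cell birth and
#'   division-or-terminal times in minutes at 20 degrees C, on the Sulston
#'   scale (time 0 = birth of P0). All embryos are warped onto this timing
#'   standard before expression profiles are compared. The packaged timings
#'   are self-consistent synthetic values calibrated to the classic staging
#'   landmarks (4-cell stage shortly after the second cleavage round, live
#'   count 100 at minute 145, live count 200 at minute 175) rather than a
#'   transcription of any published timing table.
#' @name canonical-lineage
NULL

.CANONICAL_HORIZON <- 260 # end of the covered window (comma stage), minutes

# AB cells whose branch ends in programmed cell death in the packaged model
.CANONICAL_DEATHS <- c("ABalaaaaaa", "ABaraaaaaa", "ABplaaaaaa", "ABpraaaaaa")

#' Build the packaged canonical lineage
#'
#' Constructs the full reference tree: AB to generation 8 after AB (256
#' cells), MS to 64, E and C to 32, D to 8, plus Z2/Z3, covering minutes 0
#' to 260. Division rounds are staggered by small per-cell offsets (in
#' lexicographic name order) so that every integer stage in the profiling
#' window is actually attained; sister cells are always born together.
#'
#' @return a `canonical_lineage` object: data.frame with columns `name`,
#'   `birth_min`, `end_min`, `terminal`, `death`.
#' @examples
#' lin <- build_canonical_lineage()
#' length(cells_alive_at(lin, 175))  # 200
#' @export
build_canonical_lineage <- function() {
  rows <- list()
  add <- function(name, birth, end, terminal = FALSE, death = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, birth_min = birth, end_min = end,
      terminal = terminal, death = death, stringsAsFactors = FALSE
    )
  }

  # founder chain
  add("P0", 0, 15); add("AB", 15, 30); add("P1", 15, 32)
  add("EMS", 32, 50); add("P2", 32, 54)
  add("MS", 50, 70); add("E", 50, 75); add("C", 54, 76)
  add("P3", 54, 74); add("D", 74, 110); add("P4", 74, 130)
  add("Z2", 130, .CANONICAL_HORIZON, terminal = TRUE)
  add("Z3", 130, .CANONICAL_HORIZON, terminal = TRUE)

  # a division round: mothers (named, with known division times) produce the
  # next generation; `divide` maps ordered daughter names to division times,
  # or NULL for a terminal generation.
  round_of <- function(mothers, mother_div, divide = NULL,
                       terminal_end = .CANONICAL_HORIZON) {
    kids <- character(0); births <- numeric(0)
    for (i in seq_along(mothers)) {
      d <- daughters_of(mothers[i])
      kids <- c(kids, d)
      births <- c(births, rep(mother_div[i], 2L))
    }
    ord <- order(kids)
    kids <- kids[ord]; births <- births[ord]
    if (is.null(divide)) {
      for (i in seq_along(kids)) {
        dth <- kids[i] %in% .CANONICAL_DEATHS
        add(kids[i], births[i], if (dth) births[i] + 25 else terminal_end,
            terminal = TRUE, death = dth)
      }
    } else {
      ends <- divide(kids, births)
      for (i in seq_along(kids)) add(kids[i], births[i], ends[i])
    }
    list(names = kids, div = if (is.null(divide)) NULL else divide(kids, births))
  }
  at <- function(times) function(kids, births) times
  stagger <- function(t0, step) function(kids, births) {
    t0 + step * (seq_along(kids) - 1L)
  }
  cycle <- function(len) function(kids, births) births + len

  ab1 <- round_of("AB", 30, at(c(45, 45)))                       # ABa, ABp
  ab2 <- round_of(ab1$names, ab1$div, at(rep(60, 4)))            # ABxx
  ab3 <- round_of(ab2$names, ab2$div, at(rep(78, 8)))
  ab4 <- round_of(ab3$names, ab3$div, at(rep(96, 16)))
  ab5 <- round_of(ab4$names, ab4$div, stagger(141.125, 0.125))   # last at 145
  ab6 <- round_of(ab5$names, ab5$div, cycle(30))                 # last pair at 175
  ab7 <- round_of(ab6$names, ab6$div, cycle(35))                 # [206.125, 210]
  round_of(ab7$names, ab7$div, NULL)                             # AB gen 8: terminal

  ms1 <- round_of("MS", 70, at(c(90, 90)))
  ms2 <- round_of(ms1$names, ms1$div, at(rep(110, 4)))
  ms3 <- round_of(ms2$names, ms2$div, at(rep(131, 8)))
  ms4 <- round_of(ms3$names, ms3$div, stagger(150, 1))           # 150..165
  ms5 <- round_of(ms4$names, ms4$div, stagger(173.0, 1.1))       # 2 divisions < 175
  round_of(ms5$names, ms5$div, NULL)

  e1 <- round_of("E", 75, at(c(100, 100)))
  e2 <- round_of(e1$names, e1$div, at(rep(128, 4)))
  e3 <- round_of(e2$names, e2$div, stagger(155, 1))              # 155..162
  e4 <- round_of(e3$names, e3$div, cycle(25.5))                  # > 175
  round_of(e4$names, e4$div, NULL)

  c1 <- round_of("C", 76, at(c(98, 98)))
  c2 <- round_of(c1$names, c1$div, at(rep(122, 4)))
  c3 <- round_of(c2$names, c2$div, stagger(158, 0.5))            # 158..161.5
  c4 <- round_of(c3$names, c3$div, cycle(24.3))
  round_of(c4$names, c4$div, NULL)

  d1 <- round_of("D", 110, at(c(151, 152.3)))
  d2 <- round_of(d1$names, d1$div, stagger(190, 1))
  round_of(d2$names, d2$div, NULL)

  lin <- do.call(rbind, rows)
  rownames(lin) <- NULL
  class(lin) <- c("canonical_lineage", "data.frame")
  validate_canonical_lineage(lin)
  lin
}

#' Validate a canonical lineage table
#'
#' Checks the structural invariants: required columns; division time strictly
#' after birth; rooted at P0; every non-terminal cell has exactly its two
#' daughters present, born at the mother's division time; death-flagged cells
#' are terminal; every non-root cell's mother is present.
#'
#' @param lin canonical lineage data.frame.
#' @param warn if `TRUE`, report violations as warnings and return them
#'   invisibly instead of erroring (used by the fixture loader to log issues).
#' @return `lin` invisibly (or character vector of violations when `warn`).
#' @export
validate_canonical_lineage <- function(lin, warn = FALSE) {
  bad <- character(0)
  need <- c("name", "birth_min", "end_min", "terminal", "death")
  if (!all(need %in% names(lin))) {
    stop("canonical lineage must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(lin$name)) bad <- c(bad, "duplicated cell names")
  if (!"P0" %in% lin$name) bad <- c(bad, "not rooted at P0")
  if (any(lin$end_min <= lin$birth_min)) {
    bad <- c(bad, "division/terminal time not after birth")
  }
  if (any(lin$death & !lin$terminal)) bad <- c(bad, "death-flagged cell not terminal")
  idx <- stats::setNames(seq_len(nrow(lin)), lin$name)
  for (i in seq_len(nrow(lin))) {
    nm <- lin$name[i]
    if (!is_valid_cell_name(nm)) {
      bad <- c(bad, paste0("invalid cell name '", nm, "'"))
      next
    }
    if (nm != "P0") {
      mo <- mother_of(nm)
      j <- idx[mo]
      if (is.na(j)) {
        bad <- c(bad, paste0("mother of '", nm, "' missing"))
      } else if (abs(lin$birth_min[i] - lin$end_min[j]) > 1e-9) {
        bad <- c(bad, paste0("birth of '", nm, "' != division of '", mo, "'"))
      }
    }
    if (!lin$terminal[i]) {
      dts <- daughters_of(nm)
      if (!all(dts %in% lin$name)) {
        bad <- c(bad, paste0("non-terminal '", nm, "' lacks daughters"))
      }
    }
  }
  if (length(bad)) {
    if (warn) {
      for (b in bad) warning("canonical lineage: ", b, call. = FALSE)
      return(invisible(bad))
    }
    stop("invalid canonical lineage: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  invisible(lin)
}

#' Read / write the canonical lineage CSV fixture
#'
#' The fixture dialect has header `name,birth_min,end_min,terminal,death`
#' with logical flags encoded 0/1. The reader validates all invariants and
#' logs violations as warnings.
#'
#' @param path file path.
#' @return a `canonical_lineage` object.
#' @export
read_canonical_lineage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lin <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "birth_min", "end_min", "terminal", "death")
  if (!all(need %in% names(lin))) {
    stop("canonical lineage CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  lin$terminal <- as.logical(lin$terminal)
  lin$death <- as.logical(lin$death)
  class(lin) <- c("canonical_lineage", "data.frame")
  validate_canonical_lineage(lin, warn = TRUE)
  lin
}

#' @rdname read_canonical_lineage
#' @param lin canonical lineage to write.
#' @export
write_canonical_lineage <- function(lin, path) {
  out <- as.data.frame(lin)
  out$terminal <- as.integer(out$terminal)
  out$death <- as.integer(out$death)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged canonical lineage
#'
#' Loads (and caches) the canonical lineage shipped with the package.
#' @return a `canonical_lineage` object.
#' @export
canonical_lineage <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_canonical_lineage()
    cache
  }
})

#' Cells alive at a time point
#'
#' A cell is alive from its birth up to (but excluding) its division, or up
#' to and including its end time if terminal; death-flagged cells disappear
#' at their death time. The number of live cells is the embryo's stage.
#'
#' @param lin canonical lineage.
#' @param t time in minutes within the covered span.
#' @return character vector of live cell names.
#' @examples
#' cells_alive_at(canonical_lineage(), 0)  # "P0"
#' @export
cells_alive_at <- function(lin, t) {
  stopifnot(is.numeric(t), length(t) == 1L)
  if (t < min(lin$birth_min) || t > max(lin$end_min)) {
    stop("time ", t, " outside the lineage's covered span", call. = FALSE)
  }
  open_end <- lin$terminal & !lin$death
  alive <- lin$birth_min <= t &
    ifelse(open_end, t <= lin$end_min, t < lin$end_min)
  lin$name[alive]
}

#' Stage (live-cell count) at a time point
#'
#' @inheritParams cells_alive_at
#' @return integer stage.
#' @export
stage_at <- function(lin, t) length(cells_alive_at(lin, t))

#' Live-cell-count trajectory at event times
#'
#' @param lin canonical lineage.
#' @return data.frame with columns `time` and `stage`, one row per distinct
#'   event time (evaluated just after the event).
#' @export
stage_trajectory <- function(lin) {
  times <- sort(unique(c(lin$birth_min, lin$end_min)))
  times <- times[times <= max(lin$end_min)]
  data.frame(time = times,
             stage = vapply(times, function(t) stage_at(lin, t), integer(1)))
}

#' First time at which the embryo reaches a given stage
#'
#' @param lin canonical lineage.
#' @param stage target live-cell count.
#' @return time in minutes (the event time at which the count first equals
#'   `stage`); errors if that exact count is never attained.
#' @export
time_at_stage <- function(lin, stage) {
  traj <- stage_trajectory(lin)
  hit <- which(traj$stage == stage)
  if (!length(hit)) {
    stop("stage ", stage, " is never attained in this lineage", call. = FALSE)
  }
  traj$time[min(hit)]
}

#' Canonical cell-cycle length of a cell
#'
#' @param lin canonical lineage.
#' @param name cell name present in `lin` (must be non-terminal).
#' @return cycle length in minutes.
#' @export
canonical_cycle_length <- function(lin, name) {
  i <- match(name, lin$name)
  if (is.na(i)) stop("cell '", name, "' not in canonical lineage", call. = FALSE)
  if (lin$terminal[i]) {
    stop("cell '", name, "' is terminal; cycle length undefined", call. = FALSE)
  }
  lin$end_min[i] - lin$birth_min[i]
}
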