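#' @title Sulston cell-name algebra
#' @description Helpers for the Sulston naming convention: a cell is a founder
#'   prefix (P0, P1, P2, P3, P4, EMS, AB, MS, E, C, D, Z2, Z3) followed by a
#'   suffix string over \{a,p,l,r,d,v\}, one letter per division. The early
#'   (pre-founder) divisions follow a fixed table rather than the letter rule.
#' @name cell-names
NULL

# founder -> mother lookup (everything else strips the last suffix letter)
.founder_mothers <- c(
  AB = "P0", P1 = "P0", EMS = "P1", P2 = "P1",
  MS = "EMS", E = "EMS", C = "P2", P3 = "P2",
  D = "P3", P4 = "P3", Z2 = "P4", Z3 = "P4"
)

# mother -> (anterior/left daughter, posterior/right daughter)
.founder_daughters <- list(
  P0  = c("AB", "P1"),
  P1  = c("EMS", "P2"),
  EMS = c("MS", "E"),
  P2  = c("C", "P3"),
  P3  = c("D", "P4"),
  P4  = c("Z2", "Z3")
)

.founders <- c("P0", "P1", "P2", "P3", "P4", "EMS", "AB", "MS", "E", "C", "D",
               "Z2", "Z3")

.suffix_letters <- c("a", "p", "l", "r", "d", "v")

# founder -> all founders in its clone (descendant closure over the early
# divisions); used for fast sublineage membership tests
.founder_clone <- list(
  P0 = c("P0", "AB", "P1", "EMS", "P2", "MS", "E", "C", "P3", "D", "P4",
         "Z2", "Z3"),
  P1 = c("P1", "EMS", "P2", "MS", "E", "C", "P3", "D", "P4", "Z2", "Z3"),
  EMS = c("EMS", "MS", "E"),
  P2 = c("P2", "C", "P3", "D", "P4", "Z2", "Z3"),
  P3 = c("P3", "D", "P4", "Z2", "Z3"),
  P4 = c("P4", "Z2", "Z3"),
  AB = "AB", MS = "MS", E = "E", C = "C", D = "D", Z2 = "Z2", Z3 = "Z3"
)

# vectorized founder prefix (longest match first); NA when unknown
.founder_prefix <- function(names) {
  r <- regexpr("^(EMS|AB|MS|P0|P1|P2|P3|P4|Z2|Z3|E|C|D)", names)
  out <- rep(NA_character_, length(names))
  ok <- r > 0
  out[ok] <- substring(names[ok], 1L, attr(r, "match.length")[ok])
  out
}

# fast mother lookup for pre-validated names (no re-validation)
.mother_fast <- function(name) {
  m <- .founder_mothers[name]
  if (!is.na(m)) return(unname(m))
  substring(name, 1L, nchar(name) - 1L)
}

#' Split a cell name into founder prefix and division suffix
#'
#' @param name character scalar cell name.
#' @return list with elements `founder` and `suffix` (possibly "").
#' @keywords internal
split_cell_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  # longest founder prefix wins (EMS before E, AB before A-less prefixes)
  pref <- .founders[order(nchar(.founders), decreasing = TRUE)]
  hit <- pref[startsWith(name, pref)][1]
  if (is.na(hit)) {
    stop("invalid cell name '", name, "': unknown founder prefix", call. = FALSE)
  }
  list(founder = hit, suffix = substring(name, nchar(hit) + 1L))
}

#' Validate a Sulston cell name
#'
#' A valid name is a founder prefix plus a (possibly empty) suffix over
#' \{a,p,l,r,d,v\}. Founders P0..P4 and EMS never carry suffixes (their
#' divisions are named through the founder table), so e.g. "P0a" is invalid.
#'
#' @param name character scalar.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_valid_cell_name("ABplpp")  # TRUE
#' is_valid_cell_name("ABx")     # FALSE
#' @export
is_valid_cell_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    return(FALSE)
  }
  parts <- tryCatch(split_cell_name(name), error = function(e) NULL)
  if (is.null(parts)) return(FALSE)
  if (parts$suffix == "") return(TRUE)
  if (parts$founder %in% c("P0", "P1", "P2", "P3", "P4", "EMS", "Z2", "Z3")) {
    return(FALSE)
  }
  letters_ <- strsplit(parts$suffix, "")[[1]]
  all(letters_ %in% .suffix_letters)
}

.assert_cell_name <- function(name) {
  if (!is_valid_cell_name(name)) {
    stop("invalid cell name: '", name, "'", call. = FALSE)
  }
  invisible(name)
}

#' Mother of a cell
#'
#' Strips the final division letter, or applies the founder table for the
#' early blastomeres (AB,P1 -> P0; EMS,P2 -> P1; MS,E -> EMS; C,P3 -> P2;
#' D,P4 -> P3; Z2,Z3 -> P4).
#'
#' @param name valid cell name, not "P0".
#' @return mother cell name.
#' @examples
#' mother_of("ABplpp")  # "ABplp"
#' mother_of("E")       # "EMS"
#' @export
mother_of <- function(name) {
  .assert_cell_name(name)
  if (name == "P0") stop("P0 has no mother", call. = FALSE)
  if (name %in% names(.founder_mothers)) return(unname(.founder_mothers[name]))
  substring(name, 1L, nchar(name) - 1L)
}

#' Division axis in force for a cell
#'
#' The canonical model stores one axis per division: the founder divisions use
#' the founder table, ABa/ABp divide left/right, and all other divisions are
#' anterior/posterior. This single rule is shared by the name algebra, the
#' canonical lineage builder and the trace-merging code.
#'
#' @param name dividing (mother) cell name.
#' @return one of "founder", "lr", "ap".
#' @export
division_axis <- function(name) {
  .assert_cell_name(name)
  if (name %in% names(.founder_daughters)) return("founder")
  if (name %in% c("ABa", "ABp")) return("lr")
  "ap"
}

#' Daughters of a cell
#'
#' Returns the (anterior/left, posterior/right) daughter pair: the founder
#' table for P0..P4 and EMS, otherwise the name extended by the letter pair of
#' the division axis in force (see [division_axis()]).
#'
#' @param name valid, non-terminal cell name.
#' @return character vector of length 2, anterior/left member first.
#' @examples
#' daughters_of("ABplpp")  # c("ABplppa", "ABplppp")
#' daughters_of("EMS")     # c("MS", "E")
#' @export
daughters_of <- function(name) {
  .assert_cell_name(name)
  if (name %in% c("Z2", "Z3")) {
    stop("cell '", name, "' does not divide (no daughters)", call. = FALSE)
  }
  axis <- division_axis(name)
  if (axis == "founder") return(.founder_daughters[[name]])
  pair <- if (axis == "lr") c("l", "r") else c("a", "p")
  paste0(name, pair)
}

#' Is one cell an ancestor of another?
#'
#' @param ancestor,descendant valid cell names.
#' @param strict if `TRUE` (default) a cell is not its own ancestor.
#' @return logical scalar.
#' @export
is_ancestor <- function(ancestor, descendant, strict = TRUE) {
  .assert_cell_name(ancestor)
  .assert_cell_name(descendant)
  if (ancestor == descendant) return(!strict)
  cur <- descendant
  while (cur != "P0") {
    cur <- mother_of(cur)
    if (cur == ancestor) return(TRUE)
  }
  FALSE
}

#' Generation number of a cell (P0 = 1)
#'
#' Number of cells on the path P0 -> name, inclusive.
#' @param name valid cell name.
#' @return integer generation.
#' @export
cell_generation <- function(name) {
  .assert_cell_name(name)
  g <- 1L
  cur <- name
  while (cur != "P0") {
    cur <- mother_of(cur)
    g <- g + 1L
  }
  g
}

#' Bilateral (left/right) partner of a cell name, if one exists
#'
#' Swaps every l with r in the suffix; names without an l/r letter are their
#' own partner. Used by the optional symmetry diagnostic on expression calls.
#'
#' @param name valid cell name.
#' @return partner cell name.
#' @export
bilateral_partner <- function(name) {
  .assert_cell_name(name)
  parts <- split_cell_name(name)
  paste0(parts$founder, chartr("lr", "rl", parts$suffix))
}
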