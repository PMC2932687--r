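#' @title Forward tracking, backward tracing and trace merging
#' @description Greedy nearest-neighbour frame-to-frame linking with a hard
#'   displacement cap, as in per-frame lineage tracing: a disappearing
#'   nucleus replaced by two new nearby nuclei is a division; ambiguous
#'   links (two candidates equally near within tolerance) fail loudly
#'   rather than being resolved silently. Late expressing lineages missed
#'   by forward tracking are recovered by tracing expressing nuclei
#'   backward until they meet the forward tree, then merging.
#' @name tracking-link
NULL

.dist2 <- function(p, q) {
  # p: n x 3, q: m x 3 -> n x m squared distances
  outer(rowSums(p^2), rowSums(q^2), "+") - 2 * (p %*% t(q))
}

# maximum-cardinality, minimum-cost bipartite matching on a sparse candidate
# list; exact per connected component (components are tiny), greedy fallback
# for pathologically large ones. When several near-optimal matchings exist
# the tie is broken by motion coherence: each candidate matching is scored
# by how well its implied velocities extrapolate onto the following frame.
.match_links <- function(cand, dd, Praw = NULL, C = NULL, C2 = NULL,
                         eps = 1.5, look_cap = 6) {
  np <- max(cand[, 1]); nc <- max(cand[, 2])
  link_of_prev <- rep(NA_integer_, np)
  link_of_cur <- rep(NA_integer_, nc)
  # connected components over the candidate graph
  comp_p <- rep(0L, np); comp_c <- rep(0L, nc); ncomp <- 0L
  for (q in seq_len(nrow(cand))) {
    i <- cand[q, 1]; j <- cand[q, 2]
    a <- comp_p[i]; b <- comp_c[j]
    if (a == 0L && b == 0L) {
      ncomp <- ncomp + 1L; comp_p[i] <- ncomp; comp_c[j] <- ncomp
    } else if (a == 0L) comp_p[i] <- b
    else if (b == 0L) comp_c[j] <- a
    else if (a != b) { comp_p[comp_p == b] <- a; comp_c[comp_c == b] <- a }
  }
  lookahead <- function(sel) {
    if (is.null(C2) || !length(sel)) return(0)
    tot <- 0
    for (q in sel) {
      pred <- 2 * C[cand[q, 2], ] - Praw[cand[q, 1], ]
      d2 <- sqrt(pmax(0, min(.dist2(matrix(pred, 1), C2))))
      tot <- tot + min(d2, look_cap)
    }
    tot
  }
  for (cp in unique(comp_p[comp_p > 0L])) {
    qs <- which(comp_p[cand[, 1]] == cp)
    Is <- unique(cand[qs, 1]); Js <- unique(cand[qs, 2])
    if (length(qs) > 24L) {
      ord <- qs[order(dd[qs])]                    # fallback: greedy
      for (q in ord) {
        i <- cand[q, 1]; j <- cand[q, 2]
        if (is.na(link_of_prev[i]) && is.na(link_of_cur[j])) {
          link_of_prev[i] <- j; link_of_cur[j] <- i
        }
      }
      next
    }
    # exact search: maximize matches, minimize cost; keep every matching
    # within eps of the optimum for coherence tie-breaking
    cands_of <- lapply(Is, function(i) qs[cand[qs, 1] == i])
    best_n <- -1L; best_cost <- Inf
    pool <- list()
    used <- stats::setNames(rep(FALSE, length(Js)), Js)
    sel <- integer(0)
    recurse <- function(k, n, cost) {
      remaining <- length(Is) - k + 1L
      if (n + remaining < best_n) return(invisible(NULL))
      if (n + remaining == best_n && cost > best_cost + eps) {
        return(invisible(NULL))
      }
      if (k > length(Is)) {
        if (n > best_n) {
          best_n <<- n; best_cost <<- cost
          pool <<- list(list(sel = sel, cost = cost))
        } else if (n == best_n && cost <= best_cost + eps) {
          if (cost < best_cost) best_cost <<- cost
          pool <<- c(pool, list(list(sel = sel, cost = cost)))
        }
        return(invisible(NULL))
      }
      for (q in cands_of[[k]]) {
        j <- as.character(cand[q, 2])
        if (used[j]) next
        used[j] <<- TRUE; sel <<- c(sel, q)
        recurse(k + 1L, n + 1L, cost + dd[q])
        used[j] <<- FALSE; sel <<- sel[-length(sel)]
      }
      recurse(k + 1L, n, cost)                    # leave track k unmatched
    }
    recurse(1L, 0L, 0)
    pool <- Filter(function(m) m$cost <= best_cost + eps, pool)
    best_sel <- if (length(pool) > 1L) {
      score <- vapply(pool, function(m) m$cost + lookahead(m$sel),
                      numeric(1))
      pool[[which.min(score)]]$sel
    } else pool[[1L]]$sel
    for (q in best_sel) {
      link_of_prev[cand[q, 1]] <- cand[q, 2]
      link_of_cur[cand[q, 2]] <- cand[q, 1]
    }
  }
  list(link_of_prev = link_of_prev, link_of_cur = link_of_cur)
}

#' Track nuclei forward through time
#'
#' Links nuclei frame to frame by greedy nearest neighbour within
#' `params$max_disp`. New nuclei appearing within `params$division_radius`
#' of a track are interpreted as division daughters (the mother's own
#' continuation link, if any, becomes the second daughter); a track that
#' ends with a single nearby appearance is bridged as the same cell. The
#' tree is truncated once the live-cell count exceeds `up_to_stage`.
#'
#' @param records `nuclei_table`.
#' @param params [link_params()].
#' @param up_to_stage stop tracking once more than this many nuclei are
#'   live (default `Inf`).
#' @return `tracked_tree` (names unassigned; see [assign_tree_names()]).
#' @export
forward_track <- function(records, params = link_params(),
                          up_to_stage = Inf, predict = TRUE) {
  records <- as_nuclei_table(as.data.frame(records))
  frames <- sort(unique(records$time))
  rows_by_frame <- split(seq_len(nrow(records)), records$time)
  first <- rows_by_frame[[as.character(frames[1])]]
  if (length(first) > 4L) {
    stop("embryo must start with at most 4 nuclei (found ", length(first),
         ")", call. = FALSE)
  }

  n_rec <- nrow(records)
  rec_cell <- rep(NA_integer_, n_rec)
  cell_parent <- integer(0)
  new_cell <- function(parent) {
    cell_parent[length(cell_parent) + 1L] <<- parent
    length(cell_parent)
  }
  # active tracks at current frame: record row index + cell id; the row at
  # the previous frame feeds constant-velocity prediction
  act_rows <- first
  act_cell <- vapply(first, function(r) new_cell(NA_integer_), integer(1))
  act_prev <- rep(NA_integer_, length(first))
  rec_cell[act_rows] <- act_cell

  for (k in seq_len(length(frames) - 1L)) {
    t1 <- frames[k + 1L]
    cur_rows <- rows_by_frame[[as.character(t1)]]
    P <- as.matrix(records[act_rows, c("x", "y", "z")])
    # constant-velocity prediction: a dividing daughter relaxing onto its
    # new position moves persistently, so linking against the raw last
    # position would confuse it with its (nearly stationary) sister
    hasv <- if (predict) !is.na(act_prev) else rep(FALSE, length(act_prev))
    if (any(hasv)) {
      Pprev <- as.matrix(records[ifelse(hasv, act_prev, act_rows),
                                 c("x", "y", "z")])
      step <- P - Pprev
      # extrapolate only tracks in directed motion (division relaxation);
      # predicting stationary wobble would double its noise
      moving <- hasv & sqrt(rowSums(step^2)) > 1.5
      P[moving, ] <- P[moving, , drop = FALSE] + step[moving, , drop = FALSE]
    }
    C <- as.matrix(records[cur_rows, c("x", "y", "z")])
    D2 <- .dist2(P, C)
    D2[D2 < 0] <- 0
    cap2 <- params$max_disp^2

    cand <- which(D2 <= cap2, arr.ind = TRUE)
    link_of_prev <- rep(NA_integer_, length(act_rows))   # -> index into cur
    link_of_cur <- rep(NA_integer_, length(cur_rows))    # -> index into prev
    if (nrow(cand)) {
      nxt <- rows_by_frame[[as.character(t1 + 1L)]]
      C2 <- if (is.null(nxt)) NULL else
        as.matrix(records[nxt, c("x", "y", "z")])
      Praw <- as.matrix(records[act_rows, c("x", "y", "z")])
      m <- .match_links(cand, sqrt(D2[cand]), Praw = Praw, C = C, C2 = C2)
      link_of_prev <- m$link_of_prev
      length(link_of_prev) <- length(act_rows)
      link_of_cur <- m$link_of_cur
      length(link_of_cur) <- length(cur_rows)
      # ambiguity: an unmatched candidate equally near an accepted link
      dd <- sqrt(D2[cand])
      for (q in seq_len(nrow(cand))) {
        i <- cand[q, 1]; j <- cand[q, 2]
        if (is.na(link_of_prev[i]) || link_of_prev[i] != j) next
        rival <- which(cand[, 1] == i & cand[, 2] != j &
                         is.na(link_of_cur[cand[, 2]]) &
                         abs(dd - dd[q]) < params$ambiguity_tol)
        if (length(rival)) {
          stop("ambiguous link at timepoint ", t1, ": nuclei id ",
               records$id[cur_rows[j]], " and id ",
               records$id[cur_rows[cand[rival[1], 2]]],
               " are equally near track of id ", records$id[act_rows[i]],
               call. = FALSE)
        }
      }
    }

    appearances <- which(is.na(link_of_cur))
    # attribute appearances to nearby previous-frame nuclei by globally
    # greedy distance, respecting each track's remaining daughter capacity
    # (an ended track can absorb two daughters, a continued track one more)
    mother_of_app <- rep(NA_integer_, length(appearances))
    if (length(appearances)) {
      capacity <- ifelse(is.na(link_of_prev), 2L, 1L)
      D2a <- D2[, appearances, drop = FALSE]
      pair <- which(D2a <= params$division_radius^2, arr.ind = TRUE)
      if (length(pair)) {
        pair <- pair[order(D2a[pair]), , drop = FALSE]
        for (q in seq_len(nrow(pair))) {
          i <- pair[q, 1]; a <- pair[q, 2]
          if (!is.na(mother_of_app[a]) || capacity[i] == 0L) next
          mother_of_app[a] <- i
          capacity[i] <- capacity[i] - 1L
        }
        # local improvement: moves (to a free nearer mother), swaps, and
        # an augmenting step for stranded appearances; greedy alone
        # misassigns daughters when several nearby mothers divide in the
        # same frame
        repeat {
          improved <- FALSE
          for (a in seq_along(appearances)) {
            i <- mother_of_app[a]
            if (is.na(i)) next
            alt <- pair[pair[, 2] == a & pair[, 1] != i, 1]
            alt <- alt[capacity[alt] > 0L]
            if (length(alt)) {
              j <- alt[which.min(D2a[alt, a])]
              if (D2a[j, a] < D2a[i, a]) {
                mother_of_app[a] <- j
                capacity[j] <- capacity[j] - 1L
                capacity[i] <- capacity[i] + 1L
                improved <- TRUE
              }
            }
          }
          for (a in seq_along(appearances)) {
            i <- mother_of_app[a]
            if (is.na(i)) next
            for (b in seq_along(appearances)) {
              j <- mother_of_app[b]
              if (is.na(j) || j == i) next
              ok_aj <- any(pair[, 2] == a & pair[, 1] == j)
              ok_bi <- any(pair[, 2] == b & pair[, 1] == i)
              if (ok_aj && ok_bi &&
                  D2a[j, a] + D2a[i, b] < D2a[i, a] + D2a[j, b] - 1e-12) {
                mother_of_app[a] <- j
                mother_of_app[b] <- i
                i <- j
                improved <- TRUE
              }
            }
          }
          for (a in which(is.na(mother_of_app))) {
            cand_m <- pair[pair[, 2] == a, 1]
            done <- FALSE
            for (i in cand_m) {
              for (b in which(mother_of_app == i)) {
                alt <- pair[pair[, 2] == b & pair[, 1] != i, 1]
                alt <- alt[capacity[alt] > 0L]
                if (length(alt)) {
                  j <- alt[which.min(D2a[alt, b])]
                  mother_of_app[b] <- j
                  capacity[j] <- capacity[j] - 1L
                  mother_of_app[a] <- i
                  done <- TRUE
                  improved <- TRUE
                  break
                }
              }
              if (done) break
            }
          }
          if (!improved) break
        }
      }
    }

    # decide the cell for every current-frame nucleus
    cur_cell <- rep(NA_integer_, length(cur_rows))
    linked <- which(!is.na(link_of_cur))
    cur_cell[linked] <- act_cell[link_of_cur[linked]]

    for (i in unique(mother_of_app[!is.na(mother_of_app)])) {
      apps <- appearances[which(mother_of_app == i)]
      apps <- apps[order(D2[i, apps])]
      mother_cell <- act_cell[i]
      if (is.na(link_of_prev[i])) {
        if (length(apps) == 1L) {
          cur_cell[apps] <- mother_cell              # gap bridge
        } else {
          cur_cell[apps[1]] <- new_cell(mother_cell) # division
          cur_cell[apps[2]] <- new_cell(mother_cell)
        }
      } else {
        # continuation plus an appearance: reinterpret as a division
        cont <- link_of_prev[i]
        cur_cell[cont] <- new_cell(mother_cell)
        cur_cell[apps[1]] <- new_cell(mother_cell)
      }
    }
    # leftovers (no mother in range) start parentless tracks
    for (j in which(is.na(cur_cell))) cur_cell[j] <- new_cell(NA_integer_)

    rec_cell[cur_rows] <- cur_cell
    # previous row of each continued track, for velocity prediction
    cont_prev <- rep(NA_integer_, length(cur_rows))
    for (j in seq_along(cur_rows)) {
      i <- link_of_cur[j]
      if (!is.na(i) && cur_cell[j] == act_cell[i]) cont_prev[j] <- act_rows[i]
    }
    rec_cell[cur_rows] <- cur_cell
    act_rows <- cur_rows
    act_cell <- cur_cell
    act_prev <- cont_prev
    if (length(act_rows) > up_to_stage) break
  }

  keep <- !is.na(rec_cell)
  rec <- records[keep, , drop = FALSE]
  rec$cell_id <- rec_cell[keep]
  agg_min <- tapply(rec$time, rec$cell_id, min)
  agg_max <- tapply(rec$time, rec$cell_id, max)
  ids <- as.integer(names(agg_min))
  cells <- data.frame(cell_id = ids,
                      parent_id = cell_parent[ids],
                      name = NA_character_,
                      birth_tp = as.integer(agg_min),
                      end_tp = as.integer(agg_max),
                      stringsAsFactors = FALSE)
  cells <- cells[order(cells$cell_id), ]
  rownames(cells) <- NULL
  new_tracked_tree(cells, rec)
}

#' Trace expressing nuclei backward to the forward tree
#'
#' Each seed extends backward frame by frame via nearest neighbour within
#' `params$max_disp`. Two branches converging on one earlier nucleus are
#' fused (a division seen in reverse) into a mother branch. A branch stops
#' as soon as its current nucleus lies within the link-acceptance distance
#' of a forward-tracked nucleus at the same timepoint; reaching the first
#' frame without meeting the forward tree is an unlinked-branch error.
#'
#' @param seeds data.frame with columns `time` and `id` identifying the
#'   seed records (e.g. expressing nuclei at a late timepoint).
#' @param records full `nuclei_table`.
#' @param params [link_params()].
#' @param forward `tracked_tree` from [forward_track()].
#' @return object of class `backward_branches`: a list with `branches`
#'   (per-branch record rows, children branch ids, forward attachment) and
#'   the `records` they index.
#' @export
backward_trace <- function(seeds, records, params = link_params(),
                           forward) {
  records <- as_nuclei_table(as.data.frame(records))
  link_accept <- .resolve_link_accept(params, records)
  rows_by_frame <- split(seq_len(nrow(records)), records$time)
  fwd_by_frame <- split(seq_len(nrow(forward$records)), forward$records$time)

  seed_rows <- mapply(function(tt, ii) {
    r <- which(records$time == tt & records$id == ii)
    if (!length(r)) {
      stop("seed (time ", tt, ", id ", ii, ") not found in records",
           call. = FALSE)
    }
    r[1]
  }, seeds$time, seeds$id)

  branches <- list()
  mk_branch <- function(row, seed_label) {
    branches[[length(branches) + 1L]] <<- list(
      rows = row, children = integer(0), attach = NA_integer_,
      active = TRUE, seed = seed_label
    )
    length(branches)
  }
  # forward attachment check: nearest forward record at the same timepoint
  attach_cell <- function(row) {
    tt <- records$time[row]
    f <- fwd_by_frame[[as.character(tt)]]
    if (is.null(f)) return(NA_integer_)
    p <- as.matrix(records[row, c("x", "y", "z"), drop = FALSE])
    q <- as.matrix(forward$records[f, c("x", "y", "z"), drop = FALSE])
    d2 <- .dist2(p, q)
    j <- which.min(d2)
    if (sqrt(max(0, d2[j])) <= link_accept) forward$records$cell_id[f[j]]
    else NA_integer_
  }

  for (s in seq_along(seed_rows)) {
    b <- mk_branch(seed_rows[s], paste0("time ", seeds$time[s], " id ",
                                        seeds$id[s]))
    ac <- attach_cell(seed_rows[s])
    if (!is.na(ac)) { branches[[b]]$attach <- ac; branches[[b]]$active <- FALSE }
  }

  claimed <- seed_rows
  t_min <- min(records$time)
  repeat {
    act <- which(vapply(branches, `[[`, TRUE, "active"))
    if (!length(act)) break
    cur_times <- vapply(act, function(b) records$time[utils::tail(branches[[b]]$rows, 1L)],
                        numeric(1))
    t_now <- max(cur_times)
    stepping <- act[cur_times == t_now]
    if (t_now <= t_min) {
      stop("unlinked branch: seed ", branches[[stepping[1]]]$seed,
           " reached the first timepoint without meeting the forward tree",
           call. = FALSE)
    }
    prev_rows <- rows_by_frame[[as.character(t_now - 1)]]
    if (is.null(prev_rows)) {
      stop("unlinked branch: no nuclei at timepoint ", t_now - 1, call. = FALSE)
    }
    Q <- as.matrix(records[prev_rows, c("x", "y", "z"), drop = FALSE])
    # nearest-neighbour targets, at most two branches per earlier nucleus
    # (a nucleus has at most two backward daughters); contended branches
    # fall back to their next-nearest candidate
    P <- as.matrix(records[vapply(stepping, function(b)
      utils::tail(branches[[b]]$rows, 1L), integer(1)),
      c("x", "y", "z"), drop = FALSE])
    D2 <- .dist2(P, Q)
    D2[D2 < 0] <- 0
    pair <- which(D2 <= params$max_disp^2, arr.ind = TRUE)
    if (is.null(nrow(pair))) pair <- matrix(pair, ncol = 2)
    targets <- rep(NA_integer_, length(stepping))
    if (nrow(pair)) {
      pair <- pair[order(D2[pair]), , drop = FALSE]
      taken <- integer(0)
      for (q in seq_len(nrow(pair))) {
        bi <- pair[q, 1]; tg <- prev_rows[pair[q, 2]]
        if (!is.na(targets[bi]) || sum(taken == tg) >= 2L) next
        targets[bi] <- tg
        taken <- c(taken, tg)
      }
    }
    if (anyNA(targets)) {
      b <- stepping[which(is.na(targets))[1]]
      stop("unlinked branch: seed ", branches[[b]]$seed,
           " found no nucleus within max_disp at timepoint ", t_now - 1,
           call. = FALSE)
    }
    hit_claimed <- targets %in% setdiff(claimed, targets)
    if (any(hit_claimed)) {
      stop("backward branches converge mid-trail; provide seeds at a ",
           "common timepoint", call. = FALSE)
    }
    for (tr in unique(targets)) {
      grp <- stepping[targets == tr]
      if (length(grp) >= 2L) {
        # division seen in reverse: fuse into a new mother branch
        for (b in grp) branches[[b]]$active <- FALSE
        if (length(grp) > 2L) {
          stop("more than two branches converge on one nucleus at timepoint ",
               t_now - 1, call. = FALSE)
        }
        m <- mk_branch(tr, branches[[grp[1]]]$seed)
        branches[[m]]$children <- grp
        ac <- attach_cell(tr)
        if (!is.na(ac)) { branches[[m]]$attach <- ac; branches[[m]]$active <- FALSE }
      } else {
        b <- grp
        branches[[b]]$rows <- c(branches[[b]]$rows, tr)
        ac <- attach_cell(tr)
        if (!is.na(ac)) { branches[[b]]$attach <- ac; branches[[b]]$active <- FALSE }
      }
      claimed <- c(claimed, tr)
    }
  }
  structure(list(branches = branches, records = records),
            class = "backward_branches")
}

#' Merge backward branches into the forward tree
#'
#' Each attached branch extends its forward cell with the backward-traced
#' records (the overlap with the forward track is dropped); fused branch
#' pairs become named daughters via [daughters_of()], the anterior name
#' going to the daughter with the smaller x at birth. Conflicting
#' attachments (two distinct branches on one forward terminal, or a branch
#' attached to a cell that already divided in the forward tree) are errors.
#'
#' @param forward named `tracked_tree` from [forward_track()] +
#'   [assign_tree_names()].
#' @param backward `backward_branches` from [backward_trace()].
#' @return merged `tracked_tree` (validated).
#' @export
merge_traces <- function(forward, backward) {
  cells <- forward$cells
  rec <- forward$records
  brec <- backward$records
  branches <- backward$branches

  has_fwd_kids <- function(cid) any(!is.na(cells$parent_id) &
                                      cells$parent_id == cid)
  # keep only branches that add something
  is_root <- rep(TRUE, length(branches))
  for (b in branches) is_root[b$children] <- FALSE
  roots <- which(is_root)
  useful <- vapply(roots, function(i) {
    b <- branches[[i]]
    end_tp <- cells$end_tp[match(b$attach, cells$cell_id)]
    any(brec$time[b$rows] > end_tp) || length(b$children) > 0
  }, logical(1))
  roots <- roots[useful]

  att <- vapply(roots, function(i) branches[[i]]$attach, integer(1))
  if (anyNA(att)) stop("unattached backward branch cannot be merged", call. = FALSE)
  if (anyDuplicated(att)) {
    stop("conflict: two backward branches attach to forward cell ",
         att[duplicated(att)][1], " with inconsistent divisions", call. = FALSE)
  }

  next_id <- max(cells$cell_id) + 1L
  add_records <- function(rows, cid) {
    if (!length(rows)) return(invisible(NULL))
    extra <- brec[rows, , drop = FALSE]
    extra$cell_id <- cid
    extra$name <- cells$name[match(cid, cells$cell_id)]
    if (is.na(extra$name[1])) extra$name <- ""
    rec <<- rbind(rec, extra)
  }
  birth_x_of <- function(branch) {
    rows <- branch$rows
    rows <- rows[order(brec$time[rows])]
    mean(brec$x[utils::head(rows, 5L)])
  }

  graft <- function(branch_id, cid) {
    # branch rows run late -> early; attach extends cell cid forward in time
    b <- branches[[branch_id]]
    end_tp <- cells$end_tp[match(cid, cells$cell_id)]
    rows <- rev(b$rows)
    rows <- rows[brec$time[rows] > end_tp]
    if (length(rows)) {
      tps <- brec$time[rows]
      if (tps[1] != end_tp + 1L || any(diff(tps) != 1L)) {
        stop("conflict: backward branch does not extend forward cell ", cid,
             " contiguously", call. = FALSE)
      }
      add_records(rows, cid)
      cells$end_tp[match(cid, cells$cell_id)] <<- max(tps)
    }
    if (length(b$children)) {
      if (has_fwd_kids(cid)) {
        stop("conflict: forward cell ", cid,
             " already divided but a backward branch divides it again",
             call. = FALSE)
      }
      kids <- b$children
      xs <- vapply(kids, function(k) birth_x_of(branches[[k]]), numeric(1))
      if (xs[1] == xs[2]) {
        warning("anterior/posterior tie at backward division under cell ",
                cid, call. = FALSE)
      }
      kids <- kids[order(xs)]
      mname <- cells$name[match(cid, cells$cell_id)]
      dn <- if (!is.na(mname)) daughters_of(mname) else c(NA_character_, NA_character_)
      for (z in 1:2) {
        kb <- branches[[kids[z]]]
        krows <- rev(kb$rows)
        kid_id <- next_id; next_id <<- next_id + 1L
        cells <<- rbind(cells, data.frame(
          cell_id = kid_id, parent_id = cid, name = dn[z],
          birth_tp = min(brec$time[krows]), end_tp = max(brec$time[krows]),
          stringsAsFactors = FALSE
        ))
        add_records(krows, kid_id)
        if (length(kb$children)) graft_children(kids[z], kid_id)
      }
    }
  }
  graft_children <- function(branch_id, cid) {
    b <- branches[[branch_id]]
    kids <- b$children
    xs <- vapply(kids, function(k) birth_x_of(branches[[k]]), numeric(1))
    kids <- kids[order(xs)]
    mname <- cells$name[match(cid, cells$cell_id)]
    dn <- if (!is.na(mname)) daughters_of(mname) else c(NA_character_, NA_character_)
    for (z in 1:2) {
      kb <- branches[[kids[z]]]
      krows <- rev(kb$rows)
      kid_id <- next_id; next_id <<- next_id + 1L
      cells <<- rbind(cells, data.frame(
        cell_id = kid_id, parent_id = cid, name = dn[z],
        birth_tp = min(brec$time[krows]), end_tp = max(brec$time[krows]),
        stringsAsFactors = FALSE
      ))
      add_records(krows, kid_id)
      if (length(kb$children)) graft_children(kids[z], kid_id)
    }
  }

  for (i in roots) {
    cid <- branches[[i]]$attach
    if (has_fwd_kids(cid) &&
        any(brec$time[branches[[i]]$rows] >
              cells$end_tp[match(cid, cells$cell_id)])) {
      stop("conflict: backward branch extends forward cell ", cid,
           " past its division", call. = FALSE)
    }
    graft(i, cid)
  }
  rec <- rec[order(rec$time, rec$id), ]
  rownames(rec) <- NULL
  out <- new_tracked_tree(cells, rec)
  validate_tracked_tree(out)
  out
}
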