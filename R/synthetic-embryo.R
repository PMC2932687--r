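#' @title Synthetic embryo simulator
#' @description Generates tracked-nuclei tables with full ground truth and
#'   the statistical structure the analyses assume: an invariant binary
#'   lineage with stereotyped (optionally jittered and clock-scaled)
#'   division timings, bilaterally symmetric reporter expression confined
#'   to configured posterior sublineages with onset at a configured
#'   live-cell-count stage, additive background and emission noise with an
#'   optional marginally-expressing cohort, a minimal spatial model
#'   (lattice home sites, Gaussian frame-to-frame motion, daughters placed
#'   along the anteroposterior axis) sufficient to exercise tracking, and
#'   perturbations: onset delay plus level reduction for RNAi, and
#'   subtree-timing swaps for homeotic fate transformations.
#' @name synthetic-embryo
NULL

#' Simulator configuration
#'
#' Defaults are the wild-type reporter conditions the analyses target:
#' bilaterally symmetric expression in the posterior daughters of the four
#' ABp(l/r)(a/p)p sublineages and the posterior C branches, onset at the
#' 200-cell stage, a 5:1 expressing-to-background intensity ratio, and
#' mild division-timing jitter.
#'
#' @param seed integer RNG seed; all randomness derives from it.
#' @param expressing_roots sublineage roots whose descendants express.
#' @param onset_stage live-cell count at which expression switches on.
#' @param emission_mean,emission_sd reporter emission per frame (arbitrary
#'   units), added to background in expressing cells after onset.
#' @param background_mean,background_sd per-frame background intensity.
#' @param marginal_fraction fraction of non-expressing cells given a weak
#'   marginal signal (`marginal_level`); 0 by default.
#' @param marginal_level mean added intensity of marginal cells.
#' @param timing_jitter_sd SD (minutes) of division-time jitter.
#' @param clock_scale global clock factor relative to canonical time.
#' @param spacing inter-nuclear lattice spacing (um).
#' @param motion_sd stationary SD (um) of the positional jitter around a
#'   nucleus' home site.
#' @param motion_rho frame-to-frame autocorrelation of the jitter (AR(1));
#'   nuclei wobble rather than teleport, so successive frames are
#'   correlated and the per-frame step SD is
#'   `motion_sd * sqrt(2 * (1 - motion_rho))`.
#' @param motion_common_frac fraction of the jitter variance that is an
#'   embryo-common drift (the whole tissue shifts together); the rest is
#'   per-nucleus wobble. Per-nucleus stationary SD stays `motion_sd`.
#' @param diameter nucleus diameter (um).
#' @param start_time,end_time first and last imaged minute (1-min frames).
#' @param delay_cycles RNAi perturbation: onset delay in cell cycles.
#' @param level_factor RNAi perturbation: emission multiplier in (0, 1].
#' @param swap_pairs list of c(root, donor) name pairs; the subtree under
#'   `root` adopts the donor subtree's division timings (homeotic
#'   transformation).
#' @param reporter_channel channel carrying the reporter ("red" or
#'   "green"); the other channel carries a ubiquitous lineaging marker.
#' @param canonical canonical lineage used as the timing template.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       expressing_roots = c("ABplapp", "ABplppp",
                                            "ABprapp", "ABprppp",
                                            "Cap", "Cpp"),
                       onset_stage = 200,
                       emission_mean = 500, emission_sd = 50,
                       background_mean = 100, background_sd = 15,
                       marginal_fraction = 0, marginal_level = 150,
                       timing_jitter_sd = 0.5,
                       clock_scale = 1,
                       spacing = 5, motion_sd = 0.35, motion_rho = 0.9,
                       motion_common_frac = 0.6, diameter = 3,
                       start_time = 1, end_time = 215,
                       delay_cycles = 0, level_factor = 1,
                       swap_pairs = NULL,
                       reporter_channel = "red",
                       canonical = canonical_lineage()) {
  stopifnot(onset_stage >= 1, emission_sd >= 0, background_sd >= 0,
            timing_jitter_sd >= 0, clock_scale > 0, spacing > 0,
            motion_sd >= 0, motion_common_frac >= 0, motion_common_frac <= 1)
  if (level_factor <= 0 || level_factor > 1) {
    stop("config error: level_factor must be in (0, 1]", call. = FALSE)
  }
  missing_roots <- setdiff(expressing_roots, canonical$name)
  if (length(missing_roots)) {
    stop("config error: expressing root(s) not in canonical lineage: ",
         paste(missing_roots, collapse = ", "), call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# observed (jittered / scaled / swapped) lineage timings
.sim_timings <- function(cfg) {
  can <- cfg$canonical
  # donor cycle lookup for homeotic swaps: positional address -> cycle
  swap_cycle <- list()
  if (!is.null(cfg$swap_pairs)) {
    for (pr in cfg$swap_pairs) {
      donor_map <- subtree_cycle_map(can, pr[2])
      recv <- subtree_cycle_map(can, pr[1])
      cyc <- stats::setNames(donor_map$cycle, donor_map$address)
      for (k in seq_len(nrow(recv))) {
        ad <- recv$address[k]
        if (!is.na(cyc[ad])) swap_cycle[[recv$name[k]]] <- unname(cyc[ad])
      }
    }
  }
  n <- nrow(can)
  birth <- numeric(n); endt <- numeric(n)
  idx <- stats::setNames(seq_len(n), can$name)
  for (i in seq_len(n)) {             # parents precede children in the table
    nm <- can$name[i]
    birth[i] <- if (nm == "P0") 0 else endt[idx[.mother_fast(nm)]]
    cyc <- can$end_min[i] - can$birth_min[i]
    if (!is.null(swap_cycle[[nm]])) cyc <- swap_cycle[[nm]]
    cyc <- cyc * cfg$clock_scale
    if (!can$terminal[i] && cfg$timing_jitter_sd > 0) {
      cyc <- max(1, cyc + stats::rnorm(1, 0, cfg$timing_jitter_sd))
    }
    endt[i] <- birth[i] + cyc
  }
  data.frame(name = can$name, birth_min = birth, end_min = endt,
             terminal = can$terminal, death = can$death,
             stringsAsFactors = FALSE)
}

.alive_at_frame <- function(tim, f) {
  open_end <- tim$terminal & !tim$death
  tim$birth_min <= f & ifelse(open_end, f <= tim$end_min, f < tim$end_min)
}

# descendants (inclusive) of any of the given roots; vectorized via the
# Sulston prefix property (a descendant's name extends its ancestor's,
# except across the founder table, handled by the founder clone closure)
.under_roots <- function(names, roots) {
  res <- rep(FALSE, length(names))
  founders <- .founder_prefix(names)
  for (r in roots) {
    if (r %in% names(.founder_clone)) {
      res <- res | founders %in% .founder_clone[[r]]
    } else {
      res <- res | startsWith(names, r)
    }
  }
  res
}

# effective onset minute: first frame at which the live count reaches the
# configured stage, plus the RNAi delay in local cell cycles
.sim_onset <- function(cfg, tim) {
  frames <- seq(cfg$start_time, cfg$end_time)
  # live count per frame from sorted event times: alive iff birth <= f and
  # f < end (f <= end for open-ended terminal cells)
  open_end <- tim$terminal & !tim$death
  births <- sort(tim$birth_min)
  ends_closed <- sort(tim$end_min[!open_end])
  ends_open <- sort(tim$end_min[open_end])
  counts <- findInterval(frames, births) -
    findInterval(frames, ends_closed, left.open = FALSE) -
    findInterval(frames, ends_open, left.open = TRUE)
  hit <- which(counts >= cfg$onset_stage)
  if (!length(hit)) {
    # movie ends before the onset stage: the reporter never comes on
    return(list(base = Inf, onset = Inf))
  }
  base <- frames[hit[1]]
  delay_min <- 0
  if (cfg$delay_cycles != 0) {
    expr <- .under_roots(tim$name, cfg$expressing_roots)
    i <- which(expr & !tim$terminal & tim$birth_min <= base &
                 base < tim$end_min)
    cyc <- if (length(i)) mean(tim$end_min[i] - tim$birth_min[i]) else
      30 * cfg$clock_scale
    delay_min <- cfg$delay_cycles * cyc
  }
  list(base = base, onset = base + delay_min)
}

#' Simulate one embryo
#'
#' Deterministic given the seed. Divisions occur at canonical times
#' (clock-scaled, jittered, optionally subtree-swapped); nuclei occupy
#' lattice home sites with Gaussian per-frame motion; at a division one
#' daughter keeps the mother's site and the other relaxes over a few
#' frames onto the nearest free site offset along the anteroposterior
#' axis (so the anterior daughter is always the smaller-x one).
#' Expressing cells emit background plus emission from the first frame at
#' which the live count reaches the configured onset stage; all other
#' cells emit background only.
#'
#' @param cfg [sim_config()].
#' @return list: `table` (a `nuclei_table`; `name` column left empty --
#'   naming is the tracker's job) and `truth` (`timings`, per-record
#'   `names`, `expressing`, `onset`, `onset_base`, `marginal`).
#' @export
simulate_embryo <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tim <- .sim_timings(cfg)
  expr <- .under_roots(tim$name, cfg$expressing_roots)
  marginal <- rep(FALSE, nrow(tim))
  if (cfg$marginal_fraction > 0) {
    pool <- which(!expr)
    marginal[sample(pool, round(cfg$marginal_fraction * length(pool)))] <- TRUE
  }
  on <- .sim_onset(cfg, tim)

  # lattice site allocation: sites in lattice units; daughters differ in x
  occupied <- new.env(hash = TRUE)
  key <- function(s) paste(s, collapse = ",")
  offs <- expand.grid(x = -6:6, y = -6:6, z = -6:6)
  offs <- offs[offs$x != 0, ]
  offs <- offs[order(offs$x^2 + offs$y^2 + offs$z^2, offs$x, offs$y, offs$z), ]
  offs <- as.matrix(offs)
  site <- matrix(NA_real_, nrow(tim), 3)
  appear0 <- matrix(NA_real_, nrow(tim), 3)  # position at birth (um)
  idx <- stats::setNames(seq_len(nrow(tim)), tim$name)
  site[idx["P0"], ] <- c(0, 0, 0)
  appear0[idx["P0"], ] <- c(0, 0, 0)
  occupied[[key(c(0, 0, 0))]] <- TRUE
  for (i in seq_len(nrow(tim))) {
    if (tim$terminal[i]) next
    kids <- daughters_of(tim$name[i])
    ki <- idx[kids]
    S <- site[i, ]
    Sp <- NULL
    for (q in seq_len(nrow(offs))) {
      cand <- S + offs[q, ]
      if (is.null(occupied[[key(cand)]])) { Sp <- cand; break }
    }
    if (is.null(Sp)) stop("lattice exhausted; widen the offset search")
    occupied[[key(Sp)]] <- TRUE
    # anterior daughter (first of the pair) takes the smaller-x site
    if (Sp[1] < S[1]) { site[ki[1], ] <- Sp; site[ki[2], ] <- S }
    else { site[ki[1], ] <- S; site[ki[2], ] <- Sp }
    for (k in ki) {
      keeps <- all(site[k, ] == S)
      if (keeps) {
        appear0[k, ] <- S * cfg$spacing
      } else {
        # new-site daughter first appears just beyond the mother and
        # relaxes onto its home site over the following frames
        v <- (site[k, ] - S) * cfg$spacing
        d <- sqrt(sum(v^2))
        appear0[k, ] <- S * cfg$spacing + v * min(0.4 * d, 1.5) / d
      }
    }
  }

  frames <- seq(cfg$start_time, cfg$end_time)
  rows <- vector("list", nrow(tim))
  rho <- cfg$motion_rho
  sd_com <- cfg$motion_sd * sqrt(cfg$motion_common_frac)
  sd_own <- cfg$motion_sd * sqrt(1 - cfg$motion_common_frac)
  innov_sd <- sd_own * sqrt(1 - rho^2)
  # embryo-common AR(1) drift shared by every nucleus
  common <- matrix(0, length(frames), 3)
  common[1, ] <- stats::rnorm(3, 0, sd_com)
  if (length(frames) > 1) {
    for (q in 2:length(frames)) {
      common[q, ] <- rho * common[q - 1, ] +
        stats::rnorm(3, 0, sd_com * sqrt(1 - rho^2))
    }
  }
  jit_last <- matrix(NA_real_, nrow(tim), 3)  # jitter state at a cell's end
  for (i in seq_len(nrow(tim))) {
    open_end <- tim$terminal[i] && !tim$death[i]
    f <- frames[tim$birth_min[i] <= frames &
                  (if (open_end) frames <= tim$end_min[i]
                   else frames < tim$end_min[i])]
    nf <- length(f)
    if (!nf) next
    centre <- site[i, ] * cfg$spacing
    # relax from the appearance position toward the home site at 2 um/frame
    dvec <- appear0[i, ] - centre
    dist0 <- sqrt(sum(dvec^2))
    moved <- 2 * (f - f[1])  # relaxation starts at the first imaged frame
    fac <- if (dist0 > 0) pmax(0, (dist0 - moved) / dist0) else rep(0, nf)
    nominal <- matrix(centre, nf, 3, byrow = TRUE) + outer(fac, dvec)
    # AR(1) wobble with stationary SD motion_sd; daughters inherit the
    # mother's jitter state so positions are continuous across divisions
    jit <- matrix(0, nf, 3)
    j0 <- if (tim$name[i] == "P0") stats::rnorm(3, 0, sd_own) else {
      mo <- jit_last[idx[mother_of(tim$name[i])], ]
      if (anyNA(mo)) stats::rnorm(3, 0, sd_own) else
        rho * mo + stats::rnorm(3, 0, innov_sd)
    }
    jit[1, ] <- j0
    if (nf > 1) {
      for (q in 2:nf) jit[q, ] <- rho * jit[q - 1, ] +
          stats::rnorm(3, 0, innov_sd)
    }
    jit_last[i, ] <- jit[nf, ]
    pos <- nominal + jit + common[f - cfg$start_time + 1L, , drop = FALSE]
    sig <- pmax(0, stats::rnorm(nf, cfg$background_mean, cfg$background_sd))
    if (expr[i]) {
      is_on <- f >= on$onset
      sig[is_on] <- sig[is_on] +
        pmax(0, stats::rnorm(sum(is_on),
                             cfg$emission_mean * cfg$level_factor,
                             cfg$emission_sd))
    }
    if (marginal[i]) {
      is_on <- f >= on$onset
      sig[is_on] <- sig[is_on] +
        pmax(0, stats::rnorm(sum(is_on), cfg$marginal_level,
                             cfg$emission_sd))
    }
    other <- pmax(0, stats::rnorm(nf, 300, 20))
    rows[[i]] <- data.frame(
      time = f, id = i, x = pos[, 1], y = pos[, 2], z = pos[, 3],
      diameter = cfg$diameter, name = "",
      red = if (cfg$reporter_channel == "red") sig else other,
      green = if (cfg$reporter_channel == "red") other else sig,
      truth_name = tim$name[i], stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  truth_names <- data.frame(time = tab$time, id = tab$id,
                            name = tab$truth_name, stringsAsFactors = FALSE)
  tab$truth_name <- NULL
  list(table = as_nuclei_table(tab),
       truth = list(timings = tim, names = truth_names,
                    expressing = tim$name[expr],
                    marginal = tim$name[marginal],
                    onset = on$onset, onset_base = on$base))
}

#' Simulate an expression-only embryo (no spatial tracking layer)
#'
#' Fast path used for power and calibration studies: emits per-cell
#' intensity series directly on the (jittered) true tree, skipping nucleus
#' positions. The statistical structure seen by the expression pipeline is
#' identical to [simulate_embryo()]'s.
#'
#' @param cfg [sim_config()].
#' @param cells cells to emit (default: all); non-expressing cells provide
#'   the background cohort, so keep at least 10.
#' @param minutes frame window (default `start_time:end_time`).
#' @return list: `series` (a `cell_series_set` with raw values),
#'   `timings`, `truth` (as in [simulate_embryo()]).
#' @export
simulate_expression_embryo <- function(cfg = sim_config(), cells = NULL,
                                       minutes = NULL) {
  set.seed(cfg$seed)
  tim <- .sim_timings(cfg)
  expr <- .under_roots(tim$name, cfg$expressing_roots)
  on <- .sim_onset(cfg, tim)
  if (is.null(minutes)) minutes <- seq(cfg$start_time, cfg$end_time)
  keep <- if (is.null(cells)) seq_len(nrow(tim)) else
    which(tim$name %in% cells)
  v_cell <- v_time <- v_raw <- vector("list", length(keep))
  v_id <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    open_end <- tim$terminal[i] && !tim$death[i]
    f <- minutes[tim$birth_min[i] <= minutes &
                   (if (open_end) minutes <= tim$end_min[i]
                    else minutes < tim$end_min[i])]
    if (!length(f)) next
    bg <- pmax(0, stats::rnorm(length(f), cfg$background_mean,
                               cfg$background_sd))
    if (expr[i]) {
      is_on <- f >= on$onset
      bg[is_on] <- bg[is_on] +
        pmax(0, stats::rnorm(sum(is_on),
                             cfg$emission_mean * cfg$level_factor,
                             cfg$emission_sd))
    }
    v_cell[[j]] <- rep(tim$name[i], length(f))
    v_id[[j]] <- rep(i, length(f))
    v_time[[j]] <- f
    v_raw[[j]] <- bg
  }
  series <- data.frame(cell = unlist(v_cell), cell_id = unlist(v_id),
                       time = unlist(v_time), raw = unlist(v_raw),
                       corrected = NA_real_, stringsAsFactors = FALSE)
  class(series) <- c("cell_series_set", "data.frame")
  list(series = series,
       timings = tim,
       truth = list(expressing = tim$name[expr], onset = on$onset,
                    onset_base = on$base))
}

#' Simulate an RNAi experiment (treated and control embryo sets)
#'
#' Treated embryos have expression onset delayed by `delay_cycles` local
#' cell cycles and emission multiplied by `level_factor`; controls are
#' unperturbed. All embryos share the canonical reference and differ by
#' independent timing jitter and intensity noise.
#'
#' @param cfg base [sim_config()] (its `delay_cycles`/`level_factor` are
#'   overridden per group).
#' @param n_treated,n_control embryos per group (>= 2).
#' @param delay_cycles,level_factor perturbation applied to the treated
#'   group.
#' @param cells,minutes restriction passed to
#'   [simulate_expression_embryo()].
#' @return list with `treated` and `control`: lists of expression-only
#'   embryos.
#' @export
simulate_rnai <- function(cfg = sim_config(), n_treated = 6, n_control = 6,
                          delay_cycles = 1, level_factor = 0.5,
                          cells = NULL, minutes = NULL) {
  if (n_treated < 2 || n_control < 2) {
    stop("config error: need at least 2 embryos per group", call. = FALSE)
  }
  if (level_factor <= 0) {
    stop("config error: level_factor must be positive", call. = FALSE)
  }
  one <- function(k, delay, fac) {
    ecfg <- cfg
    ecfg$seed <- cfg$seed + k
    ecfg$delay_cycles <- delay
    ecfg$level_factor <- fac
    simulate_expression_embryo(ecfg, cells = cells, minutes = minutes)
  }
  list(
    treated = lapply(seq_len(n_treated),
                     function(k) one(k, delay_cycles, level_factor)),
    control = lapply(seq_len(n_control),
                     function(k) one(500000L + k, 0, 1))
  )
}

#' Run the expression pipeline on a simulated embryo
#'
#' Background subtraction, warp fit against the canonical lineage, and
#' interpolation onto the canonical minute grid.
#'
#' @param embryo output of [simulate_expression_embryo()].
#' @param k,min_run expression-calling parameters.
#' @param canonical canonical lineage.
#' @return list: `profile` (`embryo_profile`), `calls`
#'   (`expression_calls`), `warp`, `series` (corrected).
#' @export
embryo_pipeline <- function(embryo, k = 2, min_run = 5,
                            canonical = canonical_lineage()) {
  ser <- background_subtract(embryo$series, k = k)
  warp <- fit_warp(embryo$timings, canonical)
  calls <- call_expression(ser, min_run = min_run)
  prof <- interpolate_profile(ser, warp)
  list(profile = prof, calls = calls, warp = warp, series = ser)
}
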