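test_that("warping a canonical-timed embryo is the identity on grid points", {
  fx <- fixture_expression_tree("mir-57")
  warp <- fit_warp(fx$timings)
  expect_equal(warp$global_slope, 1, tolerance = 1e-9)
  ser <- background_subtract(extract_series(fx$tree, "red"))
  prof <- interpolate_profile(ser, warp, cells = "ABplppppp")
  sub <- ser[ser$cell == "ABplppppp", ]
  expect_equal(prof$value[match(sub$time, prof$minute)], sub$corrected)
})

test_that("a global clock scale is recovered as the inverse slope", {
  can <- canonical_lineage()
  for (a in c(0.8, 1.0, 1.25)) {
    obs <- transform(can, birth_min = birth_min * a, end_min = end_min * a)
    warp <- fit_warp(obs, can)
    expect_equal(warp$global_slope, 1 / a, tolerance = 1e-6)
    expect_true(all(warp$cells$slope > 0))
  }
  # with +-1 min jitter the global slope is within 2%
  set.seed(42)
  for (a in c(0.8, 1.25)) {
    obs <- transform(can, birth_min = birth_min * a, end_min = end_min * a)
    obs$end_min <- obs$end_min + runif(nrow(obs), -1, 1)
    obs$birth_min[obs$name != "P0"] <-
      obs$end_min[match(vapply(obs$name[obs$name != "P0"], mother_of, ""),
                        obs$name)]
    warp <- fit_warp(obs, can)
    expect_equal(warp$global_slope, 1 / a, tolerance = 0.02)
  }
})

test_that("warp maps are strictly increasing on simulated embryos", {
  for (seed in 1:5) {
    emb <- simulate_expression_embryo(sim_config(seed = seed,
                                                 timing_jitter_sd = 1))
    warp <- fit_warp(emb$timings)
    expect_true(all(warp$cells$slope > 0))
    # anchor residuals: warped division times stay close to canonical
    can <- canonical_lineage()
    div <- warp$cells[warp$cells$has_div, ]
    resid <- abs((div$t0_can + div$slope * (div$t1_obs - div$t0_obs)) -
                   div$t1_can)
    expect_lt(max(resid), 1e-9)
  }
})

test_that("a linear ramp under a scaled clock interpolates exactly", {
  can <- canonical_lineage()
  a <- 1.2
  obs <- transform(can, birth_min = birth_min * a, end_min = end_min * a)
  warp <- fit_warp(obs, can)
  cell <- "ABplpppp"
  i <- match(cell, obs$name)
  tt <- seq(ceiling(obs$birth_min[i]), floor(obs$end_min[i] - 1e-9))
  ser <- data.frame(cell = cell, cell_id = 1L, time = tt,
                    raw = 2 * tt, corrected = 2 * tt)
  class(ser) <- c("cell_series_set", "data.frame")
  prof <- interpolate_profile(ser, warp)
  # value at canonical minute m equals 2 * (a * m) on interior grid points
  expect_equal(prof$value, 2 * a * prof$minute, tolerance = 1e-9)
  expect_error(interpolate_profile(ser, warp, cells = cell,
                                   minutes = c(1, 2)), "range error")
})

test_that("averaging embryos uses the common grid and sample SD", {
  p1 <- data.frame(cell = "x", minute = 1:5, value = 1:5)
  p2 <- data.frame(cell = "x", minute = 3:8, value = rep(2, 6))
  avg <- average_embryos(list(p1, p2), "x")
  expect_equal(avg$minute, 3:5)
  expect_equal(avg$mean, (c(3, 4, 5) + 2) / 2)
  expect_equal(avg$sd, apply(cbind(3:5, 2), 1, sd))
  one <- average_embryos(list(p1), "x")
  expect_equal(one$mean, p1$value)
  expect_true(all(one$sd == 0))
  expect_equal(unique(one$n), 1)
  six <- average_embryos(rep(list(p1), 6), "x")
  expect_true(all(six$sd == 0))
  expect_error(average_embryos(list(p1, transform(p1, minute = 100:104)),
                               "x"), "no-overlap")
})

test_that("onset lag is zero for identical calls and +1 on the fixtures", {
  mm <- fixture_pipeline("mir-57")
  nb <- fixture_pipeline("nob-1")
  same <- onset_lag(mm$calls, mm$calls, mm$warp, mm$warp, "ABplpppppp")
  expect_equal(same$lag_cycles, 0)
  lag <- onset_lag(nb$calls, mm$calls, nb$warp, mm$warp, "ABplpppppp")
  expect_equal(lag$lag_cycles, 1)
  expect_equal(lag$lag_min, 30)
  expect_error(onset_lag(nb$calls, mm$calls, nb$warp, mm$warp, "MSaaaa"),
               "missing onset")
})

test_that("a simulated two-cycle onset delay is recovered", {
  # image to minute 250 so the delayed onset still falls in the window
  base <- sim_config(seed = 21, timing_jitter_sd = 0.3, end_time = 250)
  ctl <- simulate_expression_embryo(base)
  trt_cfg <- base; trt_cfg$seed <- 22; trt_cfg$delay_cycles <- 2
  trt <- simulate_expression_embryo(trt_cfg)
  pc <- embryo_pipeline(ctl); pt <- embryo_pipeline(trt)
  lags <- vapply(c("ABplpppppp", "ABprpppppp"), function(cl) {
    onset_lag(pc$calls, pt$calls, pc$warp, pt$warp, cl)$lag_cycles
  }, numeric(1))
  expect_true(all(abs(lags - 2) < 0.35))
})

test_that("compare_conditions matches a hand-computed Student t", {
  x <- c(12.1, 10.4, 11.8, 13.0, 12.6, 11.1)   # printed toy table
  y <- c(9.9, 10.7, 9.1, 10.2, 8.8, 9.6)
  treated <- lapply(x, function(v) data.frame(cell = "c", minute = 215,
                                              value = v))
  control <- lapply(y, function(v) data.frame(cell = "c", minute = 215,
                                              value = v))
  res <- compare_conditions(treated, control, cells = "c", minute = 215)
  # textbook pooled-variance t statistic
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 10), tolerance = 1e-12)
})

test_that("identical groups give zero difference and p = 1", {
  profs <- lapply(1:6, function(i) data.frame(cell = "c", minute = 215,
                                              value = 10 + i))
  res <- compare_conditions(profs, profs, cells = "c")
  expect_equal(res$mean_diff, 0)
  expect_equal(res$p, 1)
  const <- lapply(1:6, function(i) data.frame(cell = "c", minute = 215,
                                              value = 5))
  res2 <- compare_conditions(const, const, cells = "c")
  expect_equal(res2$p, 1)
  expect_error(compare_conditions(profs[1], profs, cells = "c"),
               "insufficient replicates")
})
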