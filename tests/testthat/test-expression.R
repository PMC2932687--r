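toy_series <- function(values_by_cell) {
  # build a cell_series_set by hand; timepoints 1..n per cell
  rows <- lapply(seq_along(values_by_cell), function(i) {
    v <- values_by_cell[[i]]
    data.frame(cell = names(values_by_cell)[i], cell_id = i,
               time = seq_along(v), raw = v, corrected = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cell_series_set", "data.frame")
  out
}

test_that("extract_series pulls one series per cell in temporal order", {
  fx <- fixture_expression_tree("mir-57")
  ser <- extract_series(fx$tree, "red")
  expect_setequal(unique(ser$cell), fx$tree$cells$name)
  one <- ser[ser$cell == "ABplppppp", ]
  expect_false(is.unsorted(one$time))
  expect_error(extract_series(fx$tree, "blue"))
  empty <- new_tracked_tree(fx$tree$cells[0, ], fx$tree$records[0, ])
  expect_equal(nrow(extract_series(empty, "red")), 0L)
})

test_that("background subtraction removes flat background and keeps outliers", {
  ser <- toy_series(setNames(rep(list(rep(50, 10)), 12),
                             paste0("c", 1:12)))
  out <- background_subtract(ser)
  expect_true(all(out$corrected == 0))
  # idempotent on an already-flattened set
  out2 <- background_subtract(transform(out, raw = corrected))
  expect_true(all(out2$corrected == 0))
  # single bright outlier survives
  vals <- c(rep(list(rep(50, 10)), 11), list(rep(500, 10)))
  names(vals) <- paste0("c", 1:12)
  out3 <- background_subtract(toy_series(vals))
  expect_true(all(out3$corrected[out3$cell == "c12"] > 0))
  expect_true(all(out3$corrected[out3$cell != "c12"] == 0))
  expect_error(background_subtract(toy_series(list(a = 1:5))),
               "insufficient data")
})

test_that("expressing cells keep signal and background stays below 1% FP", {
  fp <- c(); fn <- c()
  for (seed in 1:10) {
    emb <- simulate_expression_embryo(
      sim_config(seed = seed, emission_mean = 500, background_mean = 100,
                 background_sd = 15, end_time = 200))
    ser <- background_subtract(emb$series)
    calls <- call_expression(ser)
    called <- calls$expressing
    is_true <- calls$cell %in% emb$truth$expressing
    # true-expressing cells alive long enough after onset to be callable
    lives_after <- vapply(seq_len(nrow(calls)), function(i) {
      emb$timings$end_min[calls$cell_id[i]] > emb$truth$onset + 5
    }, logical(1))
    fn <- c(fn, sum(is_true & lives_after & !called))
    fp <- c(fp, sum(!is_true & called) / max(1, sum(!is_true)))
  }
  expect_equal(sum(fn), 0)
  expect_lt(mean(fp), 0.01)
})

test_that("onset calling needs a sustained run and reports stage", {
  ser <- toy_series(list(zero = rep(0, 10)))
  ser$corrected <- 0
  calls <- call_expression(ser)
  expect_false(calls$expressing)
  expect_true(is.na(calls$onset_tp))
  # a 3-frame blip is not an onset at min_run 5
  blip <- toy_series(list(b = c(0, 0, 5, 5, 5, 0, 0, 0, 0, 0)))
  blip$corrected <- blip$raw
  expect_false(call_expression(blip, min_run = 5)$expressing)
  sustained <- toy_series(list(s = c(0, 0, 0, 2, 2, 2, 2, 2, 2, 0)))
  sustained$corrected <- sustained$raw
  got <- call_expression(sustained, min_run = 5,
                         stage_fun = function(t) 42L)
  expect_true(got$expressing)
  expect_equal(got$onset_tp, 4)
  expect_equal(got$onset_stage, 42L)
})

test_that("onset stage recovery stays within one division across SNRs", {
  errs <- c()
  for (snr in c(3, 5, 10)) {
    for (seed in 1:7) {
      emb <- simulate_expression_embryo(
        sim_config(seed = 100 * snr + seed, emission_mean = snr * 15,
                   emission_sd = 10, background_mean = 100,
                   background_sd = 15))
      ser <- background_subtract(emb$series)
      calls <- call_expression(ser, stage_fun = function(t)
        stage_at(canonical_lineage(), t))
      onset <- min(calls$onset_tp[calls$expressing &
                                    calls$cell %in% emb$truth$expressing],
                   na.rm = TRUE)
      true_stage <- 200
      got_stage <- stage_at(canonical_lineage(), onset)
      errs <- c(errs, abs(log2(got_stage / true_stage)))
    }
  }
  expect_lte(median(errs), 1)
})

test_that("sublineage summarization finds maximal pure roots", {
  fx <- fixture_expression_tree("mir-57")
  pp <- fixture_pipeline(fx)
  roots <- pp$summary$roots
  expect_setequal(roots, c("ABplapp", "ABplppp", "ABprapp", "ABprppp",
                           "Cap", "Cpp"))
  # mutual non-ancestry
  for (a in roots) for (b in roots) {
    if (a != b) expect_false(is_ancestor(a, b))
  }
  expect_error(summarize_sublineages(pp$calls, fx$tree, purity = 0),
               "purity")
})

test_that("lowering purity never increases the number of roots", {
  pp <- fixture_pipeline("mir-57")
  fx <- fixture_expression_tree("mir-57")
  n_roots <- vapply(c(0.95, 0.8, 0.5, 0.2),
                    function(p) length(summarize_sublineages(pp$calls,
                                                             fx$tree,
                                                             p)$roots),
                    integer(1))
  expect_false(is.unsorted(rev(n_roots)))
})

test_that("degenerate summaries behave as documented", {
  fx <- fixture_expression_tree("nob-1")
  calls <- fixture_pipeline(fx)$calls
  # every cell expressing -> single root P0
  all_on <- transform(calls, expressing = TRUE)
  expect_equal(summarize_sublineages(all_on, fx$tree)$roots, "P0")
  # exactly one expressing terminal cell -> that cell alone
  one <- transform(calls, expressing = FALSE)
  leafs <- fx$tree$cells$cell_id[!(fx$tree$cells$cell_id %in%
                                     fx$tree$cells$parent_id)]
  pick <- leafs[1]
  one$expressing[one$cell_id == pick] <- TRUE
  s <- summarize_sublineages(one, fx$tree)
  expect_equal(s$roots, fx$tree$cells$name[match(pick,
                                                 fx$tree$cells$cell_id)])
})

test_that("bilateral asymmetry is reported", {
  fx <- fixture_expression_tree("mir-57")
  calls <- fixture_pipeline(fx)$calls
  calls$expressing[calls$cell == "ABplppppp"] <- TRUE
  calls$expressing[calls$cell == "ABprppppp"] <- FALSE
  expect_warning(check_bilateral_symmetry(calls), "asymmetric")
})
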