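test_that("penetrance is exact count arithmetic with one-decimal display", {
  fx <- phenotype_fixtures()
  key <- penetrance(fx$table1, "mir-57(gk175)", "26C", "Ste")
  expect_equal(key$percent, 32.1)
  expect_equal(key$n, 978L)
  expect_equal(key$affected, 314)
  expect_equal(key$percent_raw, 100 * 314 / 978)
  # all-unaffected toy table
  toy <- data.frame(animal = 1:20, genotype = "g", condition = "c",
                    Emb = FALSE)
  expect_equal(penetrance(toy, "g", "c", "Emb")$percent, 0)
  expect_error(penetrance(toy, "nope", "c", "Emb"), "empty selection")
  expect_true(all(penetrance(fx$table2, "Pmir57_only_gk175", "20C",
                             "VabNob")$percent == 0))
})

test_that("penetrance comparison agrees with a hand-computed chi-square", {
  g <- function(n, k) data.frame(ph = c(rep(TRUE, k), rep(FALSE, n - k)))
  a <- g(978, 314); b <- g(451, 26)
  got <- compare_penetrance(a, b, "ph")
  want <- suppressWarnings(prop.test(c(314, 26), c(978, 451)))
  expect_equal(got$p, want$p.value)
  expect_equal(got$statistic, unname(want$statistic))
  # hand-computed continuity-corrected chi-square on the 2x2 table
  o <- matrix(c(314, 978 - 314, 26, 451 - 26), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi <- sum((abs(o - e) - 0.5)^2 / e)
  expect_equal(got$statistic, chi, tolerance = 1e-12)
  # identical groups: p = 1 convention
  expect_equal(compare_penetrance(a, a, "ph")$p, 1)
  expect_error(compare_penetrance(a[0, , drop = FALSE], b, "ph"),
               "nonempty")
})

test_that("high-temperature sterility is significantly elevated", {
  fx <- phenotype_fixtures()
  mut <- fx$table1[fx$table1$genotype == "mir-57(gk175)" &
                     fx$table1$condition == "26C" &
                     fx$table1$assay == "Ste", ]
  wt <- fx$table1[fx$table1$genotype == "N2" &
                    fx$table1$condition == "26C" &
                    fx$table1$assay == "Ste", ]
  res <- compare_penetrance(mut, wt, "Ste")
  expect_lt(res$p, 0.05)
  expect_gt(res$estimate[1], res$estimate[2])
})

test_that("delta-delta-Ct gives closed-form folds on clean data", {
  cts <- qpcr_fixture()
  res <- ddct_fold_change(cts, "nob-1b", "gpd-1", group = "mir57del",
                          baseline = "wt", n_boot = 50)
  expect_equal(res$fold, 2)        # one cycle earlier -> 2^1
  res2 <- ddct_fold_change(cts, "nob-1b", "gpd-1", group = "wt_array",
                           baseline = "wt", n_boot = 50)
  expect_equal(res2$fold, 0.25)    # four-fold down
  same <- ddct_fold_change(cts, "nob-1b", "gpd-1", group = "wt",
                           baseline = "wt", n_boot = 50)
  expect_equal(same$fold, 1)
  unchanged <- ddct_fold_change(cts, "nob-1a", "gpd-1", group = "mir57del",
                                baseline = "wt", n_boot = 50)
  expect_equal(unchanged$fold, 1)
  expect_error(ddct_fold_change(cts, "nob-1b", "nope", "wt", "wt"),
               "reference")
})

test_that("ddct is invariant to per-run machine drift", {
  cts <- qpcr_fixture()
  drift <- cts
  drift$ct[drift$group == "mir57del"] <- drift$ct[drift$group == "mir57del"] + 3.7
  a <- ddct_fold_change(cts, "nob-1b", "gpd-1", "mir57del", "wt", n_boot = 10)
  b <- ddct_fold_change(drift, "nob-1b", "gpd-1", "mir57del", "wt", n_boot = 10)
  expect_equal(a$fold, b$fold)
})

test_that("ddct recovers a true fold of 2 within 5% over 1000 simulations", {
  set.seed(1234)
  folds <- vapply(1:1000, function(i) {
    base <- data.frame(
      group = rep(c("a", "b"), each = 6),
      gene = rep(rep(c("tgt", "ref"), each = 3), 2),
      replicate = rep(1:3, 4),
      ct = c(rnorm(3, 23, 0.2), rnorm(3, 15, 0.2),   # group a: 1 cycle less
             rnorm(3, 24, 0.2), rnorm(3, 15, 0.2)))
    ddct_fold_change(base, "tgt", "ref", group = "a", baseline = "b",
                     n_boot = 2)$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 2) / 2, 0.05)
})

test_that("band ratios are plain loading-normalized arithmetic", {
  res <- normalized_band_ratio(c(10, 50, 20), c(2, 2, 4), reference_lane = 1)
  expect_equal(res$level, c(5, 25, 5))
  expect_equal(res$fold, c(1, 5, 1))
  same <- normalized_band_ratio(c(3, 3), c(1, 1))
  expect_true(all(same$fold == 1))
  expect_error(normalized_band_ratio(c(1, 2), c(1, 0)), "division error")
  set.seed(2)
  s <- runif(5, 1, 10); ctl <- runif(5, 1, 2)
  r <- normalized_band_ratio(s, ctl, 3)
  expect_equal(r$fold, (s / ctl) / (s[3] / ctl[3]))
})

test_that("ray summaries reproduce the printed means and SDs", {
  rays <- ray_count_fixtures()
  wt <- summarize_rays(rays$rays[rays$group == "wt"])
  expect_equal(wt$label, "8.6±1.2 (n = 57)")
  arr <- summarize_rays(rays$rays[rays$group == "mir57_promoter_array"])
  expect_equal(arr$label, "3.2±1.2 (n = 38)")
  const <- summarize_rays(rep(9L, 12))
  expect_equal(const$sd, 0)
  v <- c(3L, 5L, 9L, 9L)
  got <- summarize_rays(v)
  expect_equal(got$mean, round(mean(v), 1))
  expect_equal(got$sd, round(sqrt(sum((v - mean(v))^2) / (length(v) - 1)), 1))
  expect_error(summarize_rays(integer(0)), "empty")
  expect_error(summarize_rays(c(1.5, 2)), "integers")
})

test_that("ROI means match hand-computed pixel averages", {
  img <- matrix(7, 10, 10)
  square <- cbind(c(2, 6, 6, 2), c(2, 2, 6, 6))
  expect_equal(roi_intensity(img, square), 7)
  img2 <- matrix(0, 10, 10)
  img2[2:6, 2:6] <- 3   # rows (y) 2..6, cols (x) 2..6
  expect_equal(roi_intensity(img2, square), 3)
  half <- cbind(c(2, 6, 6, 2), c(2, 2, 4, 4))  # y limited to 2..4
  expect_equal(roi_intensity(img2, half), 3)
  expect_error(roi_intensity(img, cbind(c(-5, 20, 20), c(1, 1, 5))),
               "bounds")
  expect_error(roi_intensity(img, cbind(1:2, 1:2)), "polygon")
})

test_that("UTR-reporter simulation ranks the with-site group lowest", {
  # tail-intensity model: reporter repressed only when both the seed site
  # and the miRNA are present
  sim_line <- function(with_site, mirna_present, n = 39, seed = 1) {
    set.seed(seed)
    repression <- if (with_site && mirna_present) 0.4 else 1
    data.frame(line = paste0("L", seed),
               intensity = rnorm(n, 1000 * repression, 80))
  }
  wt_site <- sim_line(TRUE, TRUE, seed = 1)
  wt_mut <- sim_line(FALSE, TRUE, seed = 2)
  del_site <- sim_line(TRUE, FALSE, seed = 3)
  summ <- roi_group_summary(rbind(wt_site, wt_mut, del_site))
  med <- setNames(summ$median, summ$line)
  expect_lt(med[["L1"]], med[["L2"]])          # site + miRNA: repressed
  expect_lt(med[["L1"]], med[["L3"]])
  expect_gt(t.test(wt_mut$intensity, del_site$intensity)$p.value, 0.01)
})
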