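make_toy_table <- function() {
  # one nucleus drifting, never dividing, 6 frames
  data.frame(time = 1:6, id = 1L, x = seq(0, 1, length.out = 6), y = 0,
             z = 0, diameter = 3, name = "", red = 100, green = 200,
             stringsAsFactors = FALSE)
}

test_that("nuclei tables round-trip through the CSV dialect", {
  sim <- simulate_embryo(sim_config(seed = 2, end_time = 60))
  path <- withr::local_tempfile(fileext = ".csv")
  write_nuclei_table(sim$table, path)
  back <- read_nuclei_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$table),
               tolerance = 1e-12)
})

test_that("malformed nuclei tables are rejected with line numbers", {
  tab <- make_toy_table()
  path <- withr::local_tempfile(fileext = ".csv")
  tab$diameter[3] <- -1
  write.csv(tab, path, row.names = FALSE)
  expect_error(read_nuclei_table(path), "line\\(s\\) 4")
  tab <- make_toy_table()
  tab$x <- as.character(tab$x); tab$x[2] <- "oops"
  write.csv(tab, path, row.names = FALSE)
  expect_error(read_nuclei_table(path), "non-numeric 'x'")
  write.csv(make_toy_table()[, -3], path, row.names = FALSE)
  expect_error(read_nuclei_table(path), "missing column")
})

test_that("a single non-dividing nucleus yields a one-cell tree", {
  tree <- forward_track(as_nuclei_table(make_toy_table()))
  expect_equal(nrow(tree$cells), 1L)
  expect_equal(tree$cells$birth_tp, 1L)
  expect_equal(tree$cells$end_tp, 6L)
  expect_silent(validate_tracked_tree(tree))
})

test_that("tracked trees serialize to JSON and back", {
  sim <- simulate_embryo(sim_config(seed = 2, end_time = 80))
  tree <- assign_tree_names(forward_track(sim$table))
  path <- withr::local_tempfile(fileext = ".json")
  write_tracked_tree(tree, path)
  back <- read_tracked_tree(path)
  expect_equal(back$cells$name, tree$cells$name)
  expect_equal(back$records$red, tree$records$red, tolerance = 1e-12)
  expect_silent(validate_tracked_tree(back))
})

test_that("equally-near link candidates raise an ambiguity error", {
  # one track, then two nuclei exactly equidistant from it
  tab <- data.frame(time = c(1, 2, 2), id = c(1, 2, 3),
                    x = c(0, 1, -1), y = 0, z = 0, diameter = 3,
                    name = "", red = 0, green = 0)
  expect_error(forward_track(as_nuclei_table(tab), link_params()),
               "ambiguous link")
})

test_that("noise-free tracking reproduces the simulated tree exactly", {
  cfg <- sim_config(seed = 5, motion_sd = 0, timing_jitter_sd = 0,
                    end_time = 150)
  sim <- simulate_embryo(cfg)
  tree <- assign_tree_names(forward_track(sim$table))
  truth <- sim$truth$names
  tn <- truth$name[match(paste(tree$records$time, tree$records$id),
                         paste(truth$time, truth$id))]
  expect_equal(mean(tree$records$name == tn), 1)
  expect_silent(validate_tracked_tree(tree))
})

test_that("forward tracking truncates at the requested stage", {
  sim <- simulate_embryo(sim_config(seed = 5, end_time = 215))
  tree <- forward_track(sim$table, up_to_stage = 350)
  live_last <- nrow(tree_cells_at(tree, max(tree$records$time)))
  expect_true(live_last > 340)           # stopped just past the threshold
  expect_lt(max(tree$records$time), 215) # and well before the movie ends
})

test_that("backward traces stop on the forward tree and merge cleanly", {
  cfg <- sim_config(seed = 11, end_time = 215)
  sim <- simulate_embryo(cfg)
  fwd <- assign_tree_names(forward_track(sim$table, up_to_stage = 350))
  truth <- sim$truth$names
  last_f <- 215
  expr_names <- sim$truth$expressing
  seeds_nm <- truth[truth$time == last_f & truth$name %in% expr_names, ]
  seeds <- data.frame(time = seeds_nm$time, id = seeds_nm$id)
  br <- backward_trace(seeds, sim$table, link_params(), fwd)
  merged <- merge_traces(fwd, br)
  expect_silent(validate_tracked_tree(merged))
  expect_equal(max(merged$records$time), last_f)
  # named accuracy of the merged expressing cells
  mrec <- merged$records
  tn <- truth$name[match(paste(mrec$time, mrec$id),
                         paste(truth$time, truth$id))]
  ok <- mrec$name == tn
  expect_gt(mean(tapply(ok, mrec$cell_id, function(v) mean(v) > 0.5)), 0.95)
})

test_that("re-merging a fully-forward-tracked embryo changes nothing", {
  cfg <- sim_config(seed = 4, end_time = 120)
  sim <- simulate_embryo(cfg)
  fwd <- assign_tree_names(forward_track(sim$table))
  tail_f <- max(sim$table$time)
  seeds <- sim$table[sim$table$time == tail_f, c("time", "id")][1:5, ]
  br <- backward_trace(seeds, sim$table, link_params(), fwd)
  merged <- merge_traces(fwd, br)
  expect_equal(nrow(merged$cells), nrow(fwd$cells))
  expect_equal(nrow(merged$records), nrow(fwd$records))
})

test_that("a seed stranded far from every nucleus is an unlinked-branch error", {
  tab <- make_toy_table()
  tab <- rbind(tab, data.frame(time = 6, id = 99, x = 500, y = 500, z = 500,
                               diameter = 3, name = "", red = 0, green = 0))
  fwd <- forward_track(as_nuclei_table(make_toy_table()))
  expect_error(
    backward_trace(data.frame(time = 6, id = 99), as_nuclei_table(tab),
                   link_params(link_accept = 1), fwd),
    "unlinked branch")
})
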