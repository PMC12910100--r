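tiny_cfg <- function(...) {
  default_config(shapes = c("linear", "hump"), strategies = "systematic",
                 totals = 6L, noise_levels = 0.2, knowledge = "unknown",
                 extremes = TRUE, reps = 10L, master_seed = 1L, ...)
}

test_that("the grid has one row per cell and repetition, and is deterministic", {
  res <- run_grid(tiny_cfg())
  expect_equal(nrow(res), 2 * 1 * 2 * 1 * 1 * 1 * 10)  # 40 rows
  key <- paste(gradsamp:::.cell_key(res), res$rep)
  expect_false(anyDuplicated(key) > 0)
  res2 <- run_grid(tiny_cfg())
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("noiseless known-shape runs are perfectly accurate", {
  cfg <- default_config(shapes = "linear", strategies = "systematic",
                        totals = 12L, noise_levels = 0, knowledge = "known",
                        extremes = TRUE, reps = 5L, master_seed = 2L)
  res <- run_grid(cfg)
  expect_true(all(abs(res$r2_multiple - 1) < 1e-12))
  expect_true(all(abs(res$neg_rmse) < 1e-8))
  expect_false(any(res$failed))
})

test_that("grid rows can be reproduced from their recorded seeds", {
  cfg <- default_config(shapes = "logistic", strategies = "pref_slope",
                        totals = 12L, noise_levels = 0.2,
                        knowledge = "unknown", extremes = FALSE,
                        reps = 5L, master_seed = 9L)
  res <- run_grid(cfg)
  sh <- response_shape("logistic")
  for (i in c(1L, 7L, nrow(res))) {
    row <- res[i, ]
    set.seed(row$seed)
    p <- place_locations("pref_slope", row$n_locations, sh, row$extremes)
    s <- draw_samples(sh, p, row$n_replicates, noise_model(row$noise))
    fit <- select_model(s, row$knowledge, sh)
    sc <- score_grid(predict_curve(fit, sh))
    expect_equal(fit$order, row$selected_order)
    expect_equal(unname(sc), c(row$r2_multiple, row$chalcraft_ps, row$neg_rmse),
                 tolerance = 1e-12)
  }
})

test_that("summaries match a two-pass oracle", {
  res <- run_grid(tiny_cfg())
  sm <- summarize_grid(res)
  expect_equal(nrow(sm), 4L)  # 2 shapes x 2 procedures
  for (i in seq_len(nrow(sm))) {
    sel <- res$shape == sm$shape[i] & res$n_replicates == sm$n_replicates[i]
    expect_equal(sm$r2_multiple_mean[i], sum(res$r2_multiple[sel]) / sum(sel),
                 tolerance = 1e-12)
  }
  one <- summarize_grid(res[1, , drop = FALSE])
  expect_equal(one$r2_multiple_mean, res$r2_multiple[1])
  expect_equal(summarize_grid(data.frame(shape = "a", strategy = "s",
                                         n_total = 6, n_locations = 3,
                                         n_replicates = 2, noise = 0.2,
                                         knowledge = "unknown", extremes = TRUE,
                                         r2_multiple = c(0.4, 0.6),
                                         chalcraft_ps = c(0.4, 0.6),
                                         neg_rmse = c(-1, -3),
                                         failed = FALSE))$r2_multiple_mean, 0.5)
})

test_that("mean accuracy does not improve with noise", {
  cfg <- default_config(shapes = "hump", strategies = "systematic",
                        totals = 48L, noise_levels = c(0.1, 0.4, 1.0),
                        knowledge = "unknown", extremes = TRUE, reps = 200L,
                        master_seed = 4L)
  res <- run_grid(cfg)
  m <- aggregate(r2_multiple ~ noise, res, mean)
  expect_true(all(diff(m$r2_multiple) < 0.01))  # non-increasing, MC slack
})

test_that("spending the budget on locations beats replication for an unknown complex shape", {
  cfg <- default_config(shapes = "logistic", strategies = "systematic",
                        totals = 48L, noise_levels = 0.2,
                        knowledge = "unknown", extremes = TRUE, reps = 200L,
                        master_seed = 5L)
  res <- run_grid(cfg)
  m <- aggregate(r2_multiple ~ n_replicates, res, mean)
  expect_gt(m$r2_multiple[m$n_replicates == 1],
            m$r2_multiple[m$n_replicates == 16])
})

test_that("interrupted runs resume without duplicating completed cells", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  cfg <- tiny_cfg()
  full <- run_grid(cfg, out_file = tmp)
  all_rows <- read.csv(tmp)
  expect_equal(nrow(all_rows), nrow(full))
  # keep only the first completed cell on disk, as after an interruption
  write.csv(all_rows[1:10, ], tmp, row.names = FALSE)
  resumed <- run_grid(cfg, out_file = tmp, resume = TRUE)
  expect_equal(nrow(resumed), nrow(full))
  expect_false(anyDuplicated(paste(gradsamp:::.cell_key(resumed), resumed$rep)) > 0)
  expect_equal(resumed$r2_multiple, full$r2_multiple, tolerance = 1e-12)
  expect_error(run_grid(cfg, out_file = tmp), "resume")
})
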