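test_that("the accuracy model recovers a built-in replication slope", {
  d <- synth_results(beta_rep = -0.01, sd_resid = 0.05, total_sd = 0.1,
                     reps = 30, seed = 101)
  f <- fit_lmm(d, 1, "r2_multiple")
  est <- f$fixef["n_replicates", "estimate"]
  se <- f$fixef["n_replicates", "se"]
  expect_lt(abs(est - (-0.01)), 3 * se)
  expect_lt(f$fixef["n_replicates", "p"], 0.05)
})

test_that("degenerate responses yield flat fits and matched R2 components", {
  d <- synth_results(beta_rep = 0, sd_resid = 0, total_sd = 0, seed = 7)
  d$r2_multiple <- 0.5
  f <- fit_lmm(d, 1, "r2_multiple")
  expect_equal(f$fixef["n_replicates", "estimate"], 0, tolerance = 1e-8)
  expect_true(is.na(f$marginal_r2) || f$marginal_r2 < 1e-6)

  # no real grouping variance: conditional ~ marginal
  d2 <- synth_results(beta_rep = -0.01, sd_resid = 0.05, total_sd = 0,
                      reps = 30, seed = 8)
  f2 <- fit_lmm(d2, 1, "r2_multiple")
  expect_lt(f2$conditional_r2 - f2$marginal_r2, 0.01)
})

test_that("Nakagawa marginal R2 reduces to OLS R2 without random structure", {
  set.seed(33)
  d <- synth_results(beta_rep = -0.02, sd_resid = 0.1, total_sd = 0,
                     reps = 30, seed = 33)
  f <- fit_lmm(d, 1, "r2_multiple")
  ols <- summary(lm(r2_multiple ~ n_replicates, d))$r.squared
  expect_equal(f$marginal_r2, ols, tolerance = 0.01)
  expect_lte(f$marginal_r2, f$conditional_r2)
  expect_lte(f$conditional_r2, 1)

  dn <- synth_results(beta_rep = 0, sd_resid = 0.2, total_sd = 0, seed = 34)
  expect_lt(fit_lmm(dn, 1, "r2_multiple")$marginal_r2, 0.01)  # pure noise
})

test_that("variation partitioning satisfies its algebraic identity", {
  d <- synth_results(beta_rep = -0.01, sd_resid = 0.1, total_sd = 0.05,
                     knowledge_gap = -0.2, reps = 20, seed = 55)
  for (joint in c("interaction", "additive")) {
    vp <- variation_partition(d, "r2_multiple", joint = joint)
    expect_equal(vp[["unique_A"]] + vp[["unique_B"]] + vp[["shared"]],
                 vp[["r2_AB"]], tolerance = 1e-10)
  }
})

test_that("orthogonal and uninformative predictors partition as expected", {
  # balanced independent factors: shared contribution ~ 0
  set.seed(66)
  n <- 10000
  d <- data.frame(shape = "s1", strategy = "g1",
                  n_total = sample(c(6, 96), n, TRUE),
                  n_locations = 3, noise = 0.2,
                  n_replicates = sample(c(1, 32), n, TRUE),
                  knowledge = sample(c("known", "unknown"), n, TRUE),
                  extremes = sample(c(TRUE, FALSE), n, TRUE),
                  rep = 1, failed = FALSE)
  d$r2_multiple <- -0.005 * d$n_replicates - 0.1 * (d$knowledge == "unknown") +
    rnorm(n, 0, 0.1)
  vp <- variation_partition(d, "r2_multiple", joint = "additive")
  expect_lt(abs(vp[["shared"]]), 0.02)
  # an uninformative second predictor has ~ zero unique contribution
  d$knowledge <- sample(c("known", "unknown"), n, TRUE)
  vp0 <- variation_partition(d, "r2_multiple", joint = "additive")
  expect_lt(abs(vp0[["unique_B"]]), 0.01)
})

test_that("effect classification flags built-in effects and respects alpha", {
  d <- synth_results(beta_rep = -0.02, sd_resid = 0.002, total_sd = 0,
                     reps = 10, seed = 77)  # slope 10x residual scale
  cl <- classify_replication_effects(d, "r2_multiple")
  expect_equal(unname(cl$percentages["negative"]), 100)
  expect_equal(sum(cl$percentages), 100)
  expect_s3_class(cl, "effect_classification")

  # flat truth: the significant share is ~ alpha across 200 cases
  dn <- synth_results(n_shapes = 40, n_strategies = 5, beta_rep = 0,
                      sd_resid = 0.1, total_sd = 0, reps = 3, seed = 78)
  cln <- classify_replication_effects(dn, "r2_multiple")
  expect_equal(cln$n_cases, 200L)
  sig <- 100 - cln$percentages[["nonsignificant"]]
  expect_lt(sig, 5 + 100 * 3 * sqrt(0.05 * 0.95 / 200))  # binomial 3-sigma
})

test_that("classification is invariant to row order", {
  d <- synth_results(n_shapes = 2, n_strategies = 2, beta_rep = -0.005,
                     sd_resid = 0.05, reps = 10, seed = 90)
  a <- classify_replication_effects(d, "r2_multiple")
  set.seed(1)
  b <- classify_replication_effects(d[sample(nrow(d)), ], "r2_multiple")
  expect_equal(a$percentages, b$percentages)
  expect_equal(a$cases$slope, b$cases$slope, tolerance = 1e-8)
})

test_that("multiple-comparison letters separate what differs and only that", {
  vals <- rep(c(0.2, 0.25, 0.22), times = 10)
  same <- compare_models(c(vals, vals), rep(c("m1", "m2"), each = 30))
  expect_equal(unname(same["m1"]), unname(same["m2"]))

  set.seed(4)
  g1 <- rnorm(20, 0, 0.01); g2 <- rnorm(20, 1, 0.01)  # 100 SDs apart
  diffl <- compare_models(c(g1, g2), rep(c("a", "b"), each = 20))
  expect_false(diffl[["a"]] == diffl[["b"]])

  perm <- sample(40)
  diffl2 <- compare_models(c(g1, g2)[perm], rep(c("a", "b"), each = 20)[perm])
  expect_equal(diffl, diffl2)
  expect_error(compare_models(g1, rep("a", 20)), "two groups")
})
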