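test_that("procedure enumeration lists every admissible factorization once", {
  p6 <- enumerate_procedures(6)
  expect_equal(p6$n_locations, c(6L, 3L))
  expect_equal(p6$n_replicates, c(1L, 2L))

  p96 <- enumerate_procedures(96)
  expect_true(any(p96$n_locations == 96 & p96$n_replicates == 1))
  expect_true(any(p96$n_locations == 3 & p96$n_replicates == 32))
  expect_false(any(p96$n_replicates > 32))

  expect_equal(enumerate_procedures(7)$n_locations, 7L)  # prime: unreplicated only

  grid <- enumerate_procedures()
  expect_equal(nrow(grid), 30L)
  expect_true(all(grid$n_total == grid$n_locations * grid$n_replicates))
  expect_true(all(grid$n_locations >= 3), TRUE)
  expect_false(any(duplicated(grid)))
  expect_true(!is.unsorted(grid$n_total))
})

test_that("criticality weights standardize, floor, and normalize", {
  lin <- response_shape("linear")
  w <- criticality_weights(lin, mode = "slope")
  expect_equal(sum(w), 1)
  expect_equal(w, rep(1 / length(w), length(w)))  # constant slope: uniform

  hump <- response_shape("hump")
  grid <- seq(1, 100, length.out = 1001)  # odd size: apex is a grid point
  ws <- criticality_weights(hump, grid, mode = "slope")
  expect_equal(sum(ws), 1)
  expect_equal(which.max(ws), 1L)  # |f'| maximal at the ends
  apex <- which.min(abs(grid - 50.5))
  expect_equal(ws[apex], min(ws))
  expect_equal(min(ws) / max(ws), 1e-3, tolerance = 1e-9)  # floored, not zero

  for (mode in c("slope", "extreme", "combined")) {
    w <- criticality_weights(hump, grid, mode = mode)
    expect_equal(sum(w), 1)
    expect_true(all(w > 0))
  }
})

test_that("systematic and log-systematic placement are exact", {
  sh <- response_shape("linear")
  expect_equal(place_locations("systematic", 3, sh, TRUE)$locations,
               c(1, 50.5, 100))
  expect_equal(place_locations("log_systematic", 3, sh, TRUE)$locations,
               c(1, 10, 100))
  # systematic placement spans the gradient ends whether or not forced
  p <- place_locations("systematic", 5, sh, FALSE)$locations
  expect_equal(range(p), c(1, 100))
  expect_equal(diff(p), rep(diff(p)[1], 4))
})

test_that("stochastic placement is in-domain, duplicate-free, seed-faithful", {
  sh <- response_shape("logistic")
  for (strat in c("random", "pref_slope", "pref_extreme", "pref_combined")) {
    set.seed(11)
    p1 <- place_locations(strat, 12, sh, FALSE)$locations
    expect_length(p1, 12)
    expect_true(all(p1 >= 1 & p1 <= 100))
    expect_false(anyDuplicated(p1) > 0)
    expect_false(is.unsorted(p1, strictly = TRUE))
    set.seed(11)
    expect_identical(place_locations(strat, 12, sh, FALSE)$locations, p1)
    set.seed(12)
    expect_false(identical(place_locations(strat, 12, sh, FALSE)$locations, p1))
    # forcing predictor extremes puts both gradient ends in, L unchanged
    set.seed(13)
    pf <- place_locations(strat, 12, sh, TRUE)$locations
    expect_length(pf, 12)
    expect_equal(range(pf), c(1, 100))
  }
  expect_error(place_locations("random", 2000, sh, FALSE), "candidate grid")
})

test_that("preferential draw frequencies converge to the criticality weights", {
  sh <- response_shape("hump")
  grid <- seq(1, 100, length.out = 1000)
  w <- criticality_weights(sh, grid, mode = "slope")
  set.seed(99)
  n_draws <- 1e6  # 1000 bins need ~1e6 single draws for TV below 0.02
  draws <- sample.int(1000, n_draws, replace = TRUE, prob = w)
  freq <- tabulate(draws, nbins = 1000) / n_draws
  tv <- sum(abs(freq - w)) / 2
  expect_lt(tv, 0.02)
})
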