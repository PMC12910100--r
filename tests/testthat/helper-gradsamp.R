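# Shared fixtures: built in code, tiny by design.

toy_samples <- function() {
  # fixed 6-point dataset reused by the least-squares oracle tests
  data.frame(x = c(5, 20, 35, 50, 75, 95),
             y = c(3.2, 18.9, 36.1, 48.7, 77.5, 93.0))
}

# independent least-squares oracle: raw-polynomial normal equations
oracle_polyfit <- function(x, y, order) {
  X <- outer(x, 0:order, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  rss <- sum(resid^2)
  n <- length(y)
  list(coef = drop(beta), rss = rss,
       aic = n * log(max(rss, 1e-12) / n) + 2 * (order + 2))
}

# synthetic results table with a known accuracy-generating process, shaped
# like a run_grid() output so the inference layer accepts it
synth_results <- function(n_shapes = 1, n_strategies = 1, reps = 20,
                          beta_rep = 0, sd_resid = 0.05,
                          total_sd = 0, knowledge_gap = 0, seed = 42) {
  set.seed(seed)
  procs <- enumerate_procedures()
  cells <- expand.grid(shape = paste0("s", seq_len(n_shapes)),
                       strategy = paste0("g", seq_len(n_strategies)),
                       proc = seq_len(nrow(procs)),
                       knowledge = c("known", "unknown"),
                       extremes = c(TRUE, FALSE),
                       rep = seq_len(reps), stringsAsFactors = FALSE)
  d <- data.frame(shape = cells$shape, strategy = cells$strategy,
                  n_total = procs$n_total[cells$proc],
                  n_locations = procs$n_locations[cells$proc],
                  n_replicates = procs$n_replicates[cells$proc],
                  noise = 0.2, knowledge = cells$knowledge,
                  extremes = cells$extremes, rep = cells$rep,
                  seed = seq_len(nrow(cells)), selected_order = 1L)
  tot_off <- stats::rnorm(length(unique(d$n_total)), 0, total_sd)
  names(tot_off) <- as.character(sort(unique(d$n_total)))
  d$r2_multiple <- beta_rep * d$n_replicates +
    tot_off[as.character(d$n_total)] +
    knowledge_gap * (d$knowledge == "unknown") +
    stats::rnorm(nrow(d), 0, sd_resid)
  d$chalcraft_ps <- d$r2_multiple
  d$neg_rmse <- d$r2_multiple
  d$failed <- FALSE
  d
}
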