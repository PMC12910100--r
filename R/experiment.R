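# Factorial simulation engine: crosses shapes x strategies x procedures x
# noise x knowledge x extremes x repetitions and scores every run.

#' Default simulation configuration
#'
#' The full factorial study conditions: all six shapes and strategies,
#' budgets {6, 12, 24, 48, 96} with every admissible locations-x-replicates
#' factorization (3..96 locations, 1..32 replicates), noise levels 20% and
#' 100%, known/unknown shape scenarios, with/without forced predictor
#' extremes, 1000 repetitions per combination.
#'
#' @param ... Named overrides of any configuration entry.
#' @return A named list (class `gradsamp_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    shapes = list_shapes(),
    strategies = .strategy_ids,
    totals = c(6L, 12L, 24L, 48L, 96L),
    min_locations = 3L,
    max_replicates = 32L,
    noise_levels = c(0.2, 1.0),
    knowledge = c("known", "unknown"),
    extremes = c(TRUE, FALSE),
    reps = 1000L,
    master_seed = 1L,
    domain = c(1, 100),
    candidate_grid_size = 1000L,
    eval_grid_size = 1000L,
    weight_floor = 1e-3,
    sd_floor_fraction = 0.01,
    max_order = 4L,
    ps_normalizer = "true_centered",
    eval_span = "domain",
    known_model = "true_shape",
    shape_params = list()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("gradsamp_config", "list"))
}

# deterministic per-(cell, rep) seed: bijective map on Z mod 2^31-1 so
# distinct (cell, rep) indices never share a seed
.child_seed <- function(master, cell_idx, rep, reps) {
  m <- 2147483647
  t <- ((cell_idx - 1) * reps + (rep - 1)) %% m
  as.integer((master %% m + (t * 16807) %% m) %% m)
}

.cell_key <- function(cells) {
  paste(cells$shape, cells$strategy, cells$n_total, cells$n_replicates,
        cells$noise, cells$knowledge, cells$extremes, sep = "|")
}

#' Run the factorial simulation grid
#'
#' For every scenario cell (shape x strategy x procedure x noise level x
#' knowledge x extremes) and repetition, the engine places locations, draws
#' noisy replicated samples, selects and fits the prediction model,
#' predicts over the full-domain evaluation grid, and scores the three
#' accuracy metrics. Rows are fully reproducible: each (cell, repetition)
#' gets its own child seed derived from `master_seed`, so any single run
#' can be re-created in isolation and results do not depend on execution
#' order.
#'
#' Numerical failures in a single run (e.g. a singular fit) are recorded
#' with `failed = TRUE` and `NA` scores; they never abort the grid.
#'
#' @param config A [default_config()] (or overrides list).
#' @param progress Print per-cell progress every `progress` cells (0 = quiet).
#' @param out_file Optional CSV path; completed cells are appended as the
#'   grid runs, so interrupted runs can be resumed.
#' @param resume If `TRUE` and `out_file` exists, cells already complete in
#'   the file are skipped and the returned table includes them.
#' @return A data.frame (class `gradsamp_results`) with one row per
#'   (cell, repetition): scenario factors, `rep`, `seed`, `selected_order`,
#'   `r2_multiple`, `chalcraft_ps`, `neg_rmse`, `failed`.
#' @export
run_grid <- function(config = default_config(), progress = 0L,
                     out_file = NULL, resume = FALSE) {
  cfg <- if (inherits(config, "gradsamp_config")) config else do.call(default_config, config)
  dom <- gradient_domain(cfg$domain[1], cfg$domain[2])
  reps <- as.integer(cfg$reps)
  if (reps < 1L) stop("reps must be >= 1")
  kmax <- as.integer(cfg$max_order)

  procs <- enumerate_procedures(cfg$totals, cfg$min_locations, cfg$max_replicates)
  cells <- expand.grid(proc_i = seq_len(nrow(procs)),
                       extremes = as.logical(cfg$extremes),
                       knowledge = as.character(cfg$knowledge),
                       noise = as.numeric(cfg$noise_levels),
                       strategy = as.character(cfg$strategies),
                       shape = as.character(cfg$shapes),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$n_total <- procs$n_total[cells$proc_i]
  cells$n_locations <- procs$n_locations[cells$proc_i]
  cells$n_replicates <- procs$n_replicates[cells$proc_i]
  n_cells <- nrow(cells)

  done_keys <- character(0)
  prior <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    if (!resume) stop("out_file exists; pass resume = TRUE to continue it")
    prior <- utils::read.csv(out_file, stringsAsFactors = FALSE)
    if (nrow(prior)) {
      tab <- table(.cell_key(prior))
      done_keys <- names(tab)[tab == reps]
      prior <- prior[.cell_key(prior) %in% done_keys, , drop = FALSE]
    }
  }
  keys <- .cell_key(cells)
  new_file <- is.null(prior) || nrow(prior) == 0L

  # per-shape precomputation: true curve, criticality weights, eval grid
  grid_n <- as.integer(cfg$eval_grid_size)
  cand_n <- as.integer(cfg$candidate_grid_size)
  shape_pre <- lapply(cfg$shapes, function(id) {
    sh <- response_shape(id, cfg$shape_params[[id]] %||% list(), dom)
    x_eval <- seq(dom$x_min, dom$x_max, length.out = grid_n)
    y_true <- sh$fun(x_eval)
    cand <- seq(dom$x_min, dom$x_max, length.out = cand_n)
    list(shape = sh, x_eval = x_eval, y_true = y_true,
         mean_true = mean(y_true), sst_true = sum((y_true - mean(y_true))^2),
         sst_raw = sum(y_true^2),
         Xg = outer(.scale_x(x_eval, dom), 0:kmax, `^`),
         cand = cand, f_cand = sh$fun(cand),
         w = list(slope = criticality_weights(sh, cand, "slope", cfg$weight_floor),
                  extreme = criticality_weights(sh, cand, "extreme", cfg$weight_floor),
                  combined = criticality_weights(sh, cand, "combined", cfg$weight_floor)),
         sd_floor = cfg$sd_floor_fraction * sh$f_range)
  })
  names(shape_pre) <- cfg$shapes

  nrow_out <- n_cells * reps
  col_order <- integer(nrow_out); col_r2 <- col_ps <- col_rmse <- rep(NA_real_, nrow_out)
  col_seed <- integer(nrow_out); col_fail <- logical(nrow_out)
  keep_row <- rep(TRUE, nrow_out)
  ps_center <- identical(cfg$ps_normalizer, "true_centered")
  eval_sampled <- match.arg(cfg$eval_span, c("domain", "sampled")) == "sampled"
  known_true <- match.arg(cfg$known_model, c("true_shape", "nominal_order")) == "true_shape"
  master <- as.numeric(cfg$master_seed)

  for (ci in seq_len(n_cells)) {
    rows <- ((ci - 1L) * reps + 1L):(ci * reps)
    if (keys[ci] %in% done_keys) { keep_row[rows] <- FALSE; next }
    cell <- cells[ci, ]
    pre <- shape_pre[[cell$shape]]
    sh <- pre$shape
    L <- cell$n_locations; r <- cell$n_replicates; N <- cell$n_total
    deterministic <- cell$strategy %in% c("systematic", "log_systematic")
    known <- cell$knowledge == "known"
    calib <- known && known_true  # known shape: calibrate y ~ a + b * f(x)
    orders <- if (calib) integer(0)
              else if (known) min(sh$nominal_order, L - 1L)
              else seq_len(min(kmax, L - 1L))
    sd_floor <- cell$noise * pre$sd_floor

    if (deterministic) {
      locs <- place_locations(cell$strategy, L, sh, cell$extremes,
                              cand_n, cfg$weight_floor)$locations
      mu_loc <- sh$fun(locs)
      sds0 <- rep(pmax(cell$noise * abs(mu_loc), sd_floor), each = r)
      mu0 <- rep(mu_loc, each = r)
      X0 <- if (calib) cbind(1, mu0)
            else outer(.scale_x(rep(locs, each = r), dom), 0:max(orders), `^`)
    }
    w_pool <- if (startsWith(cell$strategy, "pref"))
      pre$w[[sub("^pref_", "", cell$strategy)]] else NULL

    for (rep_i in seq_len(reps)) {
      row <- rows[rep_i]
      seed <- .child_seed(master, ci, rep_i, reps)
      col_seed[row] <- seed
      set.seed(seed)
      res <- tryCatch({
        if (deterministic) {
          mu <- mu0; sds <- sds0; X <- X0
          ev <- pre
        } else {
          idx <- if (is.null(w_pool)) sample(cand_n, L) else sample(cand_n, L, prob = w_pool)
          locs <- sort(pre$cand[idx])
          if (cell$extremes) { locs[1L] <- dom$x_min; locs[L] <- dom$x_max }
          mu_loc <- sh$fun(locs)
          mu <- rep(mu_loc, each = r)
          sds <- rep(pmax(cell$noise * abs(mu_loc), sd_floor), each = r)
          X <- if (calib) cbind(1, mu)
               else outer(.scale_x(rep(locs, each = r), dom), 0:max(orders), `^`)
          ev <- if (eval_sampled && !cell$extremes) {
            # accuracy is scored over the gradient span actually sampled
            xe <- seq(locs[1L], locs[L], length.out = grid_n)
            yt <- sh$fun(xe)
            mt <- mean(yt)
            list(Xg = outer(.scale_x(xe, dom), 0:kmax, `^`), y_true = yt,
                 mean_true = mt, sst_true = sum((yt - mt)^2),
                 sst_raw = sum(yt^2))
          } else pre
        }
        y <- mu + stats::rnorm(N, 0, sds)
        if (calib) {
          f <- stats::lm.fit(X, y)
          if (f$rank < 2L) stop("rank error: flat true curve at sampled locations")
          yp <- f$coefficients[1L] + f$coefficients[2L] * ev$y_true
          best_k <- 0L
        } else {
          best <- NULL; best_aic <- Inf
          for (k in orders) {
            f <- stats::lm.fit(X[, seq_len(k + 1L), drop = FALSE], y)
            if (f$rank < k + 1L) next
            rss <- sum(f$residuals^2)
            aic <- N * log(max(rss, .RSS_FLOOR) / N) + 2 * (k + 2)
            if (aic < best_aic - 1e-12) { best <- f; best_aic <- aic; best_k <- k }
          }
          if (is.null(best)) stop("rank error: no feasible order")
          yp <- drop(ev$Xg[, seq_len(best_k + 1L), drop = FALSE] %*% best$coefficients)
        }
        dev <- yp - ev$y_true
        sp <- sum((yp - mean(yp))^2)
        r2 <- if (sp <= 0) 0 else
          sum((yp - mean(yp)) * (ev$y_true - ev$mean_true))^2 / (sp * ev$sst_true)
        ps_den <- if (ps_center) ev$sst_true else ev$sst_raw
        ps <- if (ps_den <= 0) NA_real_ else 1 - sum(dev^2) / ps_den
        c(best_k, r2, ps, -sqrt(mean(dev^2)))
      }, error = function(e) NULL)
      if (is.null(res)) {
        col_fail[row] <- TRUE
      } else {
        col_order[row] <- res[1]; col_r2[row] <- res[2]
        col_ps[row] <- res[3]; col_rmse[row] <- res[4]
      }
    }
    if (!is.null(out_file)) {
      chunk <- .assemble_results(cells[ci, , drop = FALSE], reps,
                                 col_order[rows], col_r2[rows], col_ps[rows],
                                 col_rmse[rows], col_seed[rows], col_fail[rows])
      utils::write.table(chunk, out_file, sep = ",", row.names = FALSE,
                         col.names = new_file, append = !new_file, qmethod = "double")
      new_file <- FALSE
    }
    if (progress > 0L && ci %% progress == 0L)
      message(sprintf("cell %d/%d done", ci, n_cells))
  }

  out <- .assemble_results(cells, reps, col_order, col_r2, col_ps, col_rmse,
                           col_seed, col_fail)[keep_row, , drop = FALSE]
  if (!is.null(prior) && nrow(prior)) out <- rbind(prior, out)
  rownames(out) <- NULL
  class(out) <- c("gradsamp_results", "data.frame")
  attr(out, "config") <- cfg
  out
}

.assemble_results <- function(cells, reps, ord, r2, ps, rmse, seed, fail) {
  n <- nrow(cells)
  data.frame(
    shape = rep(cells$shape, each = reps),
    strategy = rep(cells$strategy, each = reps),
    n_total = rep(cells$n_total, each = reps),
    n_locations = rep(cells$n_locations, each = reps),
    n_replicates = rep(cells$n_replicates, each = reps),
    noise = rep(cells$noise, each = reps),
    knowledge = rep(cells$knowledge, each = reps),
    extremes = rep(cells$extremes, each = reps),
    rep = rep.int(seq_len(reps), n),
    seed = seed,
    selected_order = ord,
    r2_multiple = r2,
    chalcraft_ps = ps,
    neg_rmse = rmse,
    failed = fail,
    stringsAsFactors = FALSE
  )
}

#' Summarize simulation results per scenario cell
#'
#' Group means, standard deviations and counts of the accuracy metrics.
#' Failed runs are dropped (listwise) before aggregation.
#'
#' @param results A [run_grid()] table.
#' @param by Grouping columns.
#' @param metrics Metric columns to summarize.
#' @return A data.frame with one row per group: `n_runs` plus
#'   `<metric>_mean` and `<metric>_sd` for each metric.
#' @export
summarize_grid <- function(results,
                           by = c("shape", "strategy", "n_total",
                                  "n_locations", "n_replicates", "noise",
                                  "knowledge", "extremes"),
                           metrics = c("r2_multiple", "chalcraft_ps", "neg_rmse")) {
  stopifnot(nrow(results) > 0, all(by %in% names(results)),
            all(metrics %in% names(results)))
  ok <- !results$failed
  d <- results[ok, , drop = FALSE]
  g <- interaction(d[by], drop = TRUE, lex.order = TRUE)
  out <- d[match(levels(g), as.character(g)), by, drop = FALSE]
  out$n_runs <- as.integer(table(g))
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- as.numeric(tapply(d[[m]], g, mean))
    out[[paste0(m, "_sd")]] <- as.numeric(tapply(d[[m]], g, stats::sd))
  }
  rownames(out) <- NULL
  out
}

#' @exportS3Method base::print
print.gradsamp_results <- function(x, ...) {
  cat(sprintf("<gradsamp_results: %d runs, %d scenario cells, %d failed>\n",
              nrow(x), length(unique(.cell_key(x))), sum(x$failed)))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
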