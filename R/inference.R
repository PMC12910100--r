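# Statistical analysis of the simulated accuracy surface: linear mixed
# models of accuracy against replication, marginal/conditional R2,
# variation partitioning, per-case effect classification, and
# multiple-comparison letters.

.metric_cols <- c("r2_multiple", "chalcraft_ps", "neg_rmse")

#' Aggregate repetitions to per-cell mean accuracies
#'
#' Averages each accuracy metric over the repetitions of every scenario
#' cell (failed runs dropped listwise). The accuracy models operate on
#' these cell means by default: each design cell contributes one (mean)
#' accuracy value, so model tests reflect the design factors rather than
#' the Monte-Carlo repetition count.
#'
#' @param results A [run_grid()] table.
#' @param metrics Metric columns to average.
#' @return Data.frame with one row per scenario cell: factor columns,
#'   `n_reps_ok`, mean metrics, `failed = FALSE`.
#' @export
aggregate_cells <- function(results, metrics = .metric_cols) {
  d <- results[!results$failed, , drop = FALSE]
  stopifnot(nrow(d) > 0)
  by <- intersect(c("shape", "strategy", "n_total", "n_locations",
                    "n_replicates", "noise", "knowledge", "extremes"),
                  names(d))
  g <- interaction(d[by], drop = TRUE, lex.order = TRUE)
  out <- d[match(levels(g), as.character(g)), by, drop = FALSE]
  out$n_reps_ok <- as.integer(table(g))
  for (m in metrics) out[[m]] <- as.numeric(tapply(d[[m]], g, mean))
  out$failed <- FALSE
  rownames(out) <- NULL
  out
}

# grouping columns as factors, with only >1-level groupings retained
.prep_lmm_data <- function(results, metric) {
  d <- results[!results$failed & !is.na(results[[metric]]), , drop = FALSE]
  d$f_total <- factor(d$n_total)
  d$f_extremes <- factor(d$extremes)
  d$f_knowledge <- factor(d$knowledge)
  d$f_shape <- factor(d$shape)
  d
}

.model_terms <- function(model_id) {
  switch(as.character(model_id),
    "1" = list(fixed = "n_replicates",
               random = c("f_total", "f_extremes", "f_knowledge")),
    "2" = list(fixed = "n_replicates * f_extremes",
               random = c("f_total", "f_knowledge")),
    "3" = list(fixed = "n_replicates * f_knowledge",
               random = c("f_total", "f_extremes")),
    "4" = list(fixed = "n_replicates * n_total",
               random = c("f_knowledge", "f_extremes")),
    stop("model_id must be 1, 2, 3 or 4"))
}

.build_formula <- function(metric, fixed, random, data) {
  random <- c(random, "f_shape")
  keep <- vapply(random, function(v) nlevels(data[[v]]) > 1L, logical(1))
  random <- random[keep]
  if (!length(random)) stop("no random grouping with >1 level; need a mixed design")
  stats::as.formula(paste(
    metric, "~", fixed, "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")))
}

.lmer_quiet <- function(formula, data, weights = NULL) {
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore")
  suppressWarnings(suppressMessages(
    lme4::lmer(formula, data = data, REML = TRUE, weights = weights,
               control = ctrl)))
}

#' Fit one of the four accuracy models
#'
#' The four hypothesis models relating prediction accuracy to replication:
#' Model 1 `accuracy ~ replicates + (1|total) + (1|extremes) + (1|knowledge)`;
#' Model 2 crosses replicates with the gradient-length scenario (extremes)
#' as fixed effects; Model 3 with a-priori knowledge; Model 4 with total
#' sample size. Response shape enters as an additional random intercept
#' whenever more than one shape is present. Fits are REML linear mixed
#' models; `n_replicates` is numeric. Fixed effects are tested with Wald z.
#'
#' A singular fit (a variance component estimated at its zero boundary) is
#' flagged, not an error. `robust = TRUE` applies iterative Huber
#' downweighting of residuals (a sensitivity variant; the plain fit is the
#' reference analysis).
#'
#' @param results A [run_grid()] table (or compatible data.frame).
#' @param model_id 1, 2, 3 or 4.
#' @param metric Accuracy column: `"r2_multiple"`, `"chalcraft_ps"` or
#'   `"neg_rmse"`.
#' @param robust Huber-weighted refitting (3 iterations).
#' @return Object of class `gradsamp_lmm`: `fit` (the `merMod`), `fixef`
#'   (estimate/SE/z/p table), `varcomp`, `marginal_r2`, `conditional_r2`,
#'   `singular`, `model_id`, `metric`.
#' @export
fit_lmm <- function(results, model_id, metric = "r2_multiple", robust = FALSE) {
  stopifnot(metric %in% names(results))
  d <- .prep_lmm_data(results, metric)
  tm <- .model_terms(model_id)
  form <- .build_formula(metric, tm$fixed, tm$random, d)
  fit <- .lmer_quiet(form, d)
  if (robust) {
    for (i in 1:3) {
      r <- stats::residuals(fit)
      s <- stats::mad(r)
      if (s <= 0) break
      u <- abs(r / s)
      w <- ifelse(u <= 1.345, 1, 1.345 / u)
      fit <- .lmer_quiet(form, d, weights = w)
    }
  }
  .summarize_lmm(fit, model_id, metric)
}

.summarize_lmm <- function(fit, model_id, metric) {
  co <- tryCatch({
    co <- as.data.frame(suppressWarnings(summary(fit)$coefficients))
    names(co)[1:3] <- c("estimate", "se", "z")
    co
  }, error = function(e) {
    # zero-variance refits can make the covariance unavailable
    data.frame(estimate = lme4::fixef(fit), se = NA_real_, z = NA_real_)
  })
  co$p <- 2 * stats::pnorm(-abs(co$z))
  vc <- as.data.frame(lme4::VarCorr(fit))
  r2 <- r2_nakagawa(fit)
  structure(list(fit = fit, fixef = co, varcomp = vc,
                 marginal_r2 = r2[["marginal_r2"]],
                 conditional_r2 = r2[["conditional_r2"]],
                 singular = lme4::isSingular(fit, tol = 1e-5),
                 model_id = model_id, metric = metric),
            class = "gradsamp_lmm")
}

#' @exportS3Method base::print
print.gradsamp_lmm <- function(x, ...) {
  cat(sprintf("<gradsamp_lmm model %s for %s%s>\n", x$model_id, x$metric,
              if (x$singular) ", singular fit" else ""))
  print(round(x$fixef, 4))
  cat(sprintf("marginal R2 = %.4f, conditional R2 = %.4f\n",
              x$marginal_r2, x$conditional_r2))
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-component decomposition for Gaussian mixed models: the marginal
#' R2 is the variance of the fixed-effect predictions over the total
#' (fixed + summed random-intercept + residual) variance; the conditional
#' R2 adds the random-intercept variances to the numerator. Always
#' `0 <= marginal <= conditional <= 1`.
#'
#' @param fit A `merMod` or [fit_lmm()] result.
#' @return Named vector `marginal_r2`, `conditional_r2` (`NA` if the total
#'   variance is zero).
#' @export
r2_nakagawa <- function(fit) {
  if (inherits(fit, "gradsamp_lmm")) fit <- fit$fit
  mu_f <- stats::predict(fit, re.form = NA)
  var_f <- stats::var(mu_f)
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
  var_e <- stats::sigma(fit)^2
  tot <- var_f + var_r + var_e
  if (!is.finite(tot) || tot <= 0)
    return(c(marginal_r2 = NA_real_, conditional_r2 = NA_real_))
  c(marginal_r2 = var_f / tot, conditional_r2 = (var_f + var_r) / tot)
}

#' Variation partitioning between two predictors of accuracy
#'
#' Partitions the marginal R2 of a mixed model of accuracy into the unique
#' contributions of two fixed predictors and their shared contribution,
#' through nested models (Legendre-style): `unique_A = R2(AB) - R2(B)`,
#' `unique_B = R2(AB) - R2(A)`, `shared = R2(A) + R2(B) - R2(AB)`. The
#' three fractions sum to `R2(AB)` identically; a negative shared fraction
#' (suppression) is reported as-is.
#'
#' With `joint = "interaction"` (the default) the joint model crosses the
#' two predictors (`A * B`), so variance carried by their interaction is
#' attributed to the unique fractions; this matches partitioning the
#' interaction models of the accuracy analysis, where e.g. the known- and
#' unknown-shape replication slopes may have opposite signs and an additive
#' joint model would cancel them. `joint = "additive"` uses `A + B`.
#'
#' @param results A [run_grid()] table.
#' @param metric Accuracy column.
#' @param predictor_A,predictor_B Column names of the two fixed predictors
#'   (factor-valued columns are used as factors).
#' @param random Columns used as random intercepts (plus shape when it
#'   varies).
#' @param joint `"interaction"` or `"additive"` joint model.
#' @return Named vector `r2_AB`, `r2_A`, `r2_B`, `unique_A`, `unique_B`,
#'   `shared` (fractions of total variation, 0..1 scale).
#' @export
variation_partition <- function(results, metric = "r2_multiple",
                                predictor_A = "n_replicates",
                                predictor_B = "knowledge",
                                random = c("n_total", "extremes"),
                                joint = c("interaction", "additive")) {
  joint <- match.arg(joint)
  d <- .prep_lmm_data(results, metric)
  to_term <- function(v) {
    fv <- paste0("f_", sub("^n_", "", v))
    if (v %in% c("knowledge", "extremes", "shape")) paste0("f_", v)
    else if (fv %in% names(d) && v != "n_replicates" && v != "n_total") fv
    else v
  }
  rand <- vapply(random, function(v)
    if (v %in% c("n_total", "knowledge", "extremes", "shape"))
      c(n_total = "f_total", knowledge = "f_knowledge",
        extremes = "f_extremes", shape = "f_shape")[[v]] else v,
    character(1))
  a <- to_term(predictor_A); b <- to_term(predictor_B)
  marg <- function(fixed) {
    f <- .build_formula(metric, fixed, rand, d)
    r2_nakagawa(.lmer_quiet(f, d))[["marginal_r2"]]
  }
  r2_ab <- marg(paste(a, if (joint == "interaction") "*" else "+", b))
  r2_a <- marg(a)
  r2_b <- marg(b)
  c(r2_AB = r2_ab, r2_A = r2_a, r2_B = r2_b,
    unique_A = r2_ab - r2_b, unique_B = r2_ab - r2_a,
    shared = r2_a + r2_b - r2_ab)
}

#' Per-sub-fit Model 3 analysis of a results table
#'
#' For every shape-by-strategy combination at one noise level, fits
#' Model 3 (`accuracy ~ replicates * knowledge + (1|total) + (1|extremes)`),
#' records its Nakagawa marginal and conditional R2, and partitions the
#' marginal R2 between replication and a-priori knowledge. Averaging the
#' `unique_replicates` column (x100) gives replication's percent share of
#' total variation; averaging `marginal_r2` gives the Model 3 sensitivity
#' summary.
#'
#' @param results A [run_grid()] table.
#' @param metric Accuracy column.
#' @param noise_level Noise level to subset (NULL = use all rows).
#' @param aggregate Model per-cell mean accuracies instead of the raw
#'   per-repetition rows (default raw); see [aggregate_cells()].
#' @return Data.frame with one row per shape x strategy: `marginal_r2`,
#'   `conditional_r2`, `unique_replicates`, `unique_knowledge`, `shared`
#'   (fractions, 0..1).
#' @export
replication_varpart <- function(results, metric = "r2_multiple",
                                noise_level = NULL, aggregate = FALSE) {
  d <- results
  if (!is.null(noise_level)) d <- d[d$noise == noise_level, , drop = FALSE]
  stopifnot(nrow(d) > 0)
  if (aggregate) d <- aggregate_cells(d)
  combos <- unique(d[c("shape", "strategy")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- d[d$shape == combos$shape[i] & d$strategy == combos$strategy[i], ,
             drop = FALSE]
    m3 <- fit_lmm(sub, 3, metric)
    vp <- variation_partition(sub, metric, "n_replicates", "knowledge",
                              random = c("n_total", "extremes"),
                              joint = "interaction")
    data.frame(shape = combos$shape[i], strategy = combos$strategy[i],
               marginal_r2 = m3$marginal_r2,
               conditional_r2 = m3$conditional_r2,
               unique_replicates = vp[["unique_A"]],
               unique_knowledge = vp[["unique_B"]],
               shared = vp[["shared"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the effect of replication per tested case
#'
#' A "case" is one shape x strategy combination at one noise level. Per
#' case, the accuracy model accounting for a-priori knowledge (Model 3,
#' `accuracy ~ replicates * knowledge + (1|total) + (1|extremes)`) is
#' fitted to the per-repetition accuracies, and the replication effect (the
#' `n_replicates` coefficient) is classified as significantly negative,
#' significantly positive (Wald `p < alpha`), or non-significant. Cases
#' with fewer than two replicate levels are excluded and counted. Random
#' terms whose grouping has a single level in a case are dropped; a
#' degenerate mixed fit falls back to OLS.
#'
#' @param results A [run_grid()] table.
#' @param metric Accuracy column.
#' @param noise_level Noise level to subset (NULL = all rows).
#' @param alpha Significance level.
#' @param aggregate Classify per-cell mean accuracies instead of raw rows
#'   (default raw); see [aggregate_cells()].
#' @return Object of class `effect_classification`: `cases` (per-case
#'   slopes, p-values, class), `percentages` (named `negative`, `positive`,
#'   `nonsignificant`; sums to 100), `n_cases`, `n_excluded`, `alpha`.
#' @export
classify_replication_effects <- function(results, metric = "r2_multiple",
                                         noise_level = NULL, alpha = 0.05,
                                         aggregate = FALSE) {
  d <- results
  if (!is.null(noise_level)) d <- d[d$noise == noise_level, , drop = FALSE]
  d <- d[!d$failed & !is.na(d[[metric]]), , drop = FALSE]
  stopifnot(nrow(d) > 0)
  if (aggregate) d <- aggregate_cells(d)
  combos <- unique(d[c("shape", "strategy")])
  combos <- combos[order(combos$shape, combos$strategy), , drop = FALSE]
  n_excluded <- 0L
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- d[d$shape == combos$shape[i] & d$strategy == combos$strategy[i], ,
             drop = FALSE]
    if (length(unique(sub$n_replicates)) < 2L) { n_excluded <- n_excluded + 1L; next }
    sub <- .prep_lmm_data(sub, metric)
    fixed <- if (nlevels(sub$f_knowledge) > 1L) "n_replicates * f_knowledge"
             else "n_replicates"
    rand <- c("f_total", "f_extremes")[vapply(c("f_total", "f_extremes"),
               function(v) nlevels(sub[[v]]) > 1L, logical(1))]
    co <- NULL
    if (length(rand)) {
      co <- tryCatch({
        form <- stats::as.formula(paste(
          metric, "~", fixed, "+",
          paste(sprintf("(1 | %s)", rand), collapse = " + ")))
        suppressWarnings(summary(.lmer_quiet(form, sub))$coefficients)
      }, error = function(e) NULL)
    }
    if (is.null(co) || anyNA(co["n_replicates", ])) {
      fit <- stats::lm(stats::as.formula(paste(metric, "~", fixed)), sub)
      co <- summary(fit)$coefficients
    }
    slope <- co["n_replicates", 1L]
    z <- co["n_replicates", 3L]
    p <- 2 * stats::pnorm(-abs(z))
    rows[[i]] <- data.frame(combos[i, , drop = FALSE], slope = slope, p = p,
                            class = if (p >= alpha) "nonsignificant"
                                    else if (slope < 0) "negative" else "positive")
  }
  cases <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(cases) <- NULL
  pct <- 100 * c(negative = mean(cases$class == "negative"),
                 positive = mean(cases$class == "positive"),
                 nonsignificant = mean(cases$class == "nonsignificant"))
  structure(list(cases = cases, percentages = pct, n_cases = nrow(cases),
                 n_excluded = n_excluded, alpha = alpha),
            class = "effect_classification")
}

#' @exportS3Method base::print
print.effect_classification <- function(x, ...) {
  cat(sprintf("<effect_classification: %d cases (%d excluded), alpha = %g>\n",
              x$n_cases, x$n_excluded, x$alpha))
  print(round(x$percentages, 1))
  invisible(x)
}

#' Multiple-comparison letters across groups of R2 values
#'
#' One-way ANOVA across groups followed by Tukey HSD at `alpha`, summarized
#' as a compact letter display: groups sharing a letter are not
#' significantly different.
#'
#' @param values Numeric vector (e.g. one marginal R2 per shape x strategy
#'   sub-fit).
#' @param groups Grouping factor of the same length (e.g. model id), with
#'   at least two levels.
#' @param alpha Significance level.
#' @return Named character vector of letters, one per group level.
#' @export
compare_models <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups to compare")
  stopifnot(length(values) == length(groups))
  d <- data.frame(y = as.numeric(values), g = groups)
  fit <- stats::aov(y ~ g, data = d)
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  cld <- multcomp::cld(glt, level = alpha)
  letters <- cld$mcletters$Letters
  letters[levels(groups)]
}

#' Table-2-style sensitivity summary of the four models
#'
#' Fits each requested model per shape x strategy sub-fit and summarizes
#' Nakagawa marginal and conditional R2 across sub-fits (mean and SD), per
#' accuracy metric, with multiple-comparison letters across models (on
#' marginal R2) and across metrics (on conditional R2).
#'
#' @param results A [run_grid()] table (subset to one noise level for a
#'   per-noise table).
#' @param metrics Accuracy columns to include.
#' @param models Model ids to include.
#' @param aggregate Model per-cell mean accuracies instead of raw rows
#'   (default raw); see [aggregate_cells()].
#' @return List: `table` (per model x metric means/SDs), `subfits` (per
#'   sub-fit R2 values), `model_letters` (per metric), `metric_letters`
#'   (per model); letters are `NA` when fewer than two sub-fits exist.
#' @export
model_r2_table <- function(results, metrics = .metric_cols, models = 1:4,
                           aggregate = FALSE) {
  if (aggregate) results <- aggregate_cells(results)
  combos <- unique(results[c("shape", "strategy")])
  sub_rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- results[results$shape == combos$shape[i] &
                   results$strategy == combos$strategy[i], , drop = FALSE]
    for (m in metrics) for (mod in models) {
      f <- fit_lmm(sub, mod, m)
      sub_rows[[length(sub_rows) + 1L]] <-
        data.frame(shape = combos$shape[i], strategy = combos$strategy[i],
                   metric = m, model = mod, marginal_r2 = f$marginal_r2,
                   conditional_r2 = f$conditional_r2)
    }
  }
  subfits <- do.call(rbind, sub_rows)
  rownames(subfits) <- NULL
  agg <- function(v, g1, g2) {
    k <- interaction(g1, g2, drop = TRUE)
    data.frame(mean = as.numeric(tapply(v, k, mean)),
               sd = as.numeric(tapply(v, k, stats::sd)))
  }
  tab <- unique(subfits[c("metric", "model")])
  tab <- tab[order(tab$metric, tab$model), , drop = FALSE]
  for (col in c("marginal_r2", "conditional_r2")) {
    tab[[paste0(col, "_mean")]] <- vapply(seq_len(nrow(tab)), function(i)
      mean(subfits[[col]][subfits$metric == tab$metric[i] &
                          subfits$model == tab$model[i]]), numeric(1))
    tab[[paste0(col, "_sd")]] <- vapply(seq_len(nrow(tab)), function(i)
      stats::sd(subfits[[col]][subfits$metric == tab$metric[i] &
                               subfits$model == tab$model[i]]), numeric(1))
  }
  rownames(tab) <- NULL
  many <- nrow(combos) >= 2L
  model_letters <- if (many && length(models) >= 2L) {
    sapply(metrics, function(m) {
      s <- subfits[subfits$metric == m, ]
      compare_models(s$marginal_r2, s$model)
    }, simplify = FALSE)
  } else NULL
  metric_letters <- if (many && length(metrics) >= 2L) {
    sapply(models, function(mod) {
      s <- subfits[subfits$model == mod, ]
      compare_models(s$conditional_r2, s$metric)
    }, simplify = FALSE)
  } else NULL
  list(table = tab, subfits = subfits,
       model_letters = model_letters, metric_letters = metric_letters)
}
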