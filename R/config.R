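# Configuration files, validation, and the simulate -> analyze pipeline.

#' Load a simulation configuration from YAML or JSON
#'
#' Missing keys take the [default_config()] values; unknown keys and
#' unknown shape/strategy ids are rejected with the list of valid ids. An
#' empty file yields the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `gradsamp_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping of keys to values")
  cfg <- do.call(default_config, raw)
  validate_config(cfg)
}

#' Validate a configuration against the registries
#'
#' @param cfg A `gradsamp_config` or plain list of overrides.
#' @return The validated config, invisibly usable downstream.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "gradsamp_config")) cfg <- do.call(default_config, cfg)
  bad <- setdiff(cfg$shapes, list_shapes())
  if (length(bad))
    stop(sprintf("unknown shape id(s) %s; valid shapes: %s",
                 paste(bad, collapse = ", "), paste(list_shapes(), collapse = ", ")))
  bad <- setdiff(cfg$strategies, .strategy_ids)
  if (length(bad))
    stop(sprintf("unknown strategy id(s) %s; valid strategies: %s",
                 paste(bad, collapse = ", "), paste(.strategy_ids, collapse = ", ")))
  if (cfg$reps <= 0) stop("reps must be positive")
  if (length(cfg$domain) != 2 || cfg$domain[1] <= 0 || cfg$domain[1] >= cfg$domain[2])
    stop("domain must be c(x_min, x_max) with 0 < x_min < x_max")
  if (any(cfg$noise_levels < 0)) stop("noise_levels must be >= 0")
  if (!all(cfg$knowledge %in% c("known", "unknown")))
    stop("knowledge entries must be 'known' or 'unknown'")
  cfg
}

#' Serialize a configuration to YAML
#'
#' Round-trips through [load_config()].
#'
#' @param cfg A `gradsamp_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialize_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "gradsamp_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Analyze a results table and write the analysis CSV set
#'
#' Per noise level present in the results: the Table-2-style model
#' sensitivity summary (`model_r2.csv`), Model 3 variation partitioning of
#' replication vs. a-priori knowledge per shape x strategy (`varpart.csv`),
#' per-case classification of replication effects per metric
#' (`effect_classification.csv`), and multiple-comparison letters
#' (`letters.csv`; empty when fewer than two sub-fits exist).
#'
#' @param results A [run_grid()] table or path to a results CSV.
#' @param out_dir Output directory (created if missing).
#' @param metrics Accuracy columns to analyze.
#' @param models Model ids for the sensitivity summary.
#' @param alpha Significance level for the per-case classification.
#' @return Invisible named list of the written file paths.
#' @export
analyze_results <- function(results, out_dir, metrics = .metric_cols,
                            models = 1:4, alpha = 0.05) {
  if (is.character(results)) results <- utils::read.csv(results, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  noises <- sort(unique(results$noise))
  tabs <- vps <- cls <- lets <- list()
  for (nl in noises) {
    sub <- results[results$noise == nl, , drop = FALSE]
    mrt <- model_r2_table(sub, metrics = metrics, models = models)
    tabs[[length(tabs) + 1L]] <- cbind(noise = nl, mrt$table)
    for (m in metrics) {
      vp <- replication_varpart(sub, m)
      vps[[length(vps) + 1L]] <- cbind(noise = nl, metric = m, vp)
      cl <- classify_replication_effects(sub, m, alpha = alpha)
      cls[[length(cls) + 1L]] <- data.frame(
        noise = nl, metric = m, t(cl$percentages), n_cases = cl$n_cases,
        n_excluded = cl$n_excluded)
    }
    if (!is.null(mrt$model_letters)) {
      for (m in names(mrt$model_letters)) {
        lt <- mrt$model_letters[[m]]
        lets[[length(lets) + 1L]] <- data.frame(
          noise = nl, comparison = "models_on_marginal_r2", metric = m,
          group = names(lt), letter = unname(lt))
      }
    }
    if (!is.null(mrt$metric_letters)) {
      for (i in seq_along(mrt$metric_letters)) {
        lt <- mrt$metric_letters[[i]]
        lets[[length(lets) + 1L]] <- data.frame(
          noise = nl, comparison = "metrics_on_conditional_r2",
          metric = paste0("model_", models[i]),
          group = names(lt), letter = unname(lt))
      }
    }
  }
  paths <- c(model_r2 = file.path(out_dir, "model_r2.csv"),
             varpart = file.path(out_dir, "varpart.csv"),
             effect_classification = file.path(out_dir, "effect_classification.csv"),
             letters = file.path(out_dir, "letters.csv"))
  utils::write.csv(do.call(rbind, tabs), paths["model_r2"], row.names = FALSE)
  utils::write.csv(do.call(rbind, vps), paths["varpart"], row.names = FALSE)
  utils::write.csv(do.call(rbind, cls), paths["effect_classification"], row.names = FALSE)
  lets_df <- if (length(lets)) do.call(rbind, lets) else
    data.frame(noise = numeric(0), comparison = character(0),
               metric = character(0), group = character(0), letter = character(0))
  utils::write.csv(lets_df, paths["letters"], row.names = FALSE)
  invisible(as.list(paths))
}

#' Run the full simulate-then-analyze pipeline
#'
#' Simulates the configured grid (resumably, writing completed cells as it
#' goes), writes the tidy results CSV, the effective configuration, and a
#' JSON run manifest (seed, config hash, package version, timings,
#' failure counts), then runs [analyze_results()] on the output.
#'
#' @param config A `gradsamp_config`, overrides list, or path to a config
#'   file.
#' @param out_dir Output directory.
#' @param reps,seed Optional overrides of the configured repetitions and
#'   master seed.
#' @param resume Resume an interrupted `results.csv` in `out_dir`.
#' @param progress Per-cell progress interval passed to [run_grid()].
#' @return Invisible list with `results` and the analysis file paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir, reps = NULL,
                         seed = NULL, resume = FALSE, progress = 0L) {
  cfg <- if (is.character(config)) load_config(config)
         else if (inherits(config, "gradsamp_config")) config
         else do.call(default_config, config)
  if (!is.null(reps)) cfg$reps <- as.integer(reps)
  if (!is.null(seed)) cfg$master_seed <- as.integer(seed)
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results_csv <- file.path(out_dir, "results.csv")
  if (file.exists(results_csv) && !resume)
    stop(results_csv, " exists; pass resume = TRUE to continue it")
  cfg_path <- serialize_config(cfg, file.path(out_dir, "config.yaml"))
  t0 <- proc.time()[["elapsed"]]
  res <- run_grid(cfg, progress = progress, out_file = results_csv,
                  resume = resume && file.exists(results_csv))
  t1 <- proc.time()[["elapsed"]]
  paths <- analyze_results(res, out_dir)
  t2 <- proc.time()[["elapsed"]]
  manifest <- list(
    package = "gradsamp",
    version = as.character(utils::packageVersion("gradsamp")),
    master_seed = cfg$master_seed,
    reps = cfg$reps,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_runs = nrow(res),
    n_failed = sum(res$failed),
    seconds_simulate = round(t1 - t0, 2),
    seconds_analyze = round(t2 - t1, 2)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(list(results = results_csv), paths))
}

#' A tiny end-to-end smoke configuration
#'
#' One shape, one strategy, one budget, few repetitions: exercises the full
#' pipeline in seconds.
#'
#' @param reps Repetitions per cell.
#' @param seed Master seed.
#' @return A `gradsamp_config`.
#' @export
smoke_config <- function(reps = 5L, seed = 1L) {
  default_config(shapes = "hump", strategies = "systematic",
                 totals = 12L, noise_levels = 0.2, reps = as.integer(reps),
                 master_seed = as.integer(seed))
}
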