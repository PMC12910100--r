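# Sampling designs: factorizations of the sample budget into locations x
# replicates, and placement of locations along the gradient under six
# strategies.

.strategy_ids <- c("systematic", "log_systematic", "random",
                   "pref_slope", "pref_extreme", "pref_combined")

#' Enumerate sampling procedures
#'
#' A sampling procedure splits a total budget `N` into `L` distinct
#' locations times `r` replicates per location, `N = L * r`. All exact
#' factorizations with `L >= min_locations` and `r <= max_replicates` are
#' returned; a budget with no admissible factorization contributes no rows.
#'
#' @param totals Integer vector of total sample budgets.
#' @param min_locations Minimum number of distinct locations (a polynomial
#'   of degree k needs at least k + 1 of them).
#' @param max_replicates Maximum replicates per location.
#' @return A data.frame with columns `n_total`, `n_locations`,
#'   `n_replicates`, sorted by (`n_total`, `n_replicates`).
#' @examples
#' enumerate_procedures(6)   # 6x1 and 3x2
#' @export
enumerate_procedures <- function(totals = c(6L, 12L, 24L, 48L, 96L),
                                 min_locations = 3L, max_replicates = 32L) {
  totals <- as.integer(totals)
  stopifnot(all(totals >= 1L), min_locations >= 1L, max_replicates >= 1L)
  rows <- lapply(sort(unique(totals)), function(N) {
    r <- seq_len(min(max_replicates, N))
    r <- r[N %% r == 0L]
    L <- N %/% r
    keep <- L >= min_locations
    data.frame(n_total = N, n_locations = L[keep], n_replicates = r[keep])
  })
  out <- do.call(rbind, rows)
  out[order(out$n_total, out$n_replicates), , drop = FALSE]
}

#' Criticality-based sampling probabilities
#'
#' Quantifies how "critical" each candidate location is for recovering the
#' response curve: by the local slope (`|f'(x)|`), by the extremeness of the
#' response relative to the midpoint of its in-domain range
#' (`|f(x) - (min f + max f) / 2|`), or by the equal-weight mean of the two
#' min-max-standardized criticalities. The chosen criticality is min-max
#' standardized, floored at `floor_frac` of its maximum (so no candidate has
#' exactly zero probability), and normalized to sum to one. A flat
#' criticality (e.g. slope of a linear shape) yields uniform probabilities.
#'
#' @param shape A [response_shape()].
#' @param candidate_grid Coordinates to weight; defaults to a 1000-point
#'   equidistant grid over the domain.
#' @param mode One of `"slope"`, `"extreme"`, `"combined"`.
#' @param floor_frac Probability floor as a fraction of the maximum
#'   standardized weight.
#' @return Numeric probability vector over `candidate_grid` (sums to 1).
#' @export
criticality_weights <- function(shape, candidate_grid = NULL,
                                mode = c("slope", "extreme", "combined"),
                                floor_frac = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(inherits(shape, "response_shape"))
  if (is.null(candidate_grid))
    candidate_grid <- seq(shape$domain$x_min, shape$domain$x_max, length.out = 1000L)
  .check_in_domain(candidate_grid, shape$domain)
  minmax <- function(w) {
    rng <- max(w) - min(w)
    if (rng <= 1e-12 * max(abs(w), 1)) rep.int(1, length(w)) else (w - min(w)) / rng
  }
  slope_crit <- function() minmax(abs(shape$deriv(candidate_grid)))
  extreme_crit <- function() {
    mid <- (shape$f_min + shape$f_max) / 2
    minmax(abs(shape$fun(candidate_grid) - mid))
  }
  w <- switch(mode,
              slope = slope_crit(),
              extreme = extreme_crit(),
              combined = (slope_crit() + extreme_crit()) / 2)
  w <- minmax(w)
  w <- pmax(w, floor_frac * max(w))
  w / sum(w)
}

#' Place sampling locations along the gradient
#'
#' Implements the six placement strategies. Systematic places equidistant
#' locations; log-systematic places locations equidistant in log(x); random
#' draws locations uniformly without replacement from the candidate grid;
#' the preferential strategies draw without replacement with probabilities
#' from [criticality_weights()] (`pref_slope`, `pref_extreme`,
#' `pref_combined`).
#'
#' Gradient length is controlled by `extremes_included`: with extremes, the
#' two domain endpoints are always sampled (systematic grids include them by
#' construction; for random/preferential draws the smallest and largest
#' placed points are replaced by the endpoints, keeping `n_locations`
#' constant). Without extremes, nothing is forced: the systematic
#' strategies still span the ends by definition of equidistant placement,
#' while random/preferential draws cover whatever range they happen to hit
#' — the sampled gradient is then typically shorter than the full domain,
#' which is the gradient-length effect under study.
#'
#' Stochastic strategies consume the current RNG state; seed the session (or
#' pass through the experiment engine) for reproducibility.
#'
#' @param strategy One of `"systematic"`, `"log_systematic"`, `"random"`,
#'   `"pref_slope"`, `"pref_extreme"`, `"pref_combined"`.
#' @param n_locations Number of distinct locations to place (>= 2 with
#'   forced extremes, >= 3 otherwise).
#' @param shape A [response_shape()] (required; preferential strategies use
#'   its criticality, all strategies use its domain).
#' @param extremes_included Logical: force the two gradient endpoints in?
#' @param candidate_grid_size Size of the equidistant candidate grid for
#'   stochastic placement.
#' @param weight_floor Probability floor for preferential weights.
#' @return Object of class `placement` : list with `locations` (strictly
#'   increasing coordinates), `strategy_id`, `extremes_included`.
#' @examples
#' sh <- response_shape("linear")
#' place_locations("systematic", 3, sh, extremes_included = TRUE)$locations # 1 50.5 100
#' @export
place_locations <- function(strategy, n_locations, shape,
                            extremes_included = TRUE,
                            candidate_grid_size = 1000L,
                            weight_floor = 1e-3) {
  strategy <- match.arg(strategy, .strategy_ids)
  stopifnot(inherits(shape, "response_shape"))
  L <- as.integer(n_locations)
  min_L <- if (extremes_included) 2L else 3L
  if (L < min_L) stop("n_locations too small for this scenario")
  dom <- shape$domain
  a <- dom$x_min; b <- dom$x_max

  if (strategy %in% c("systematic", "log_systematic")) {
    trans <- if (strategy == "systematic") identity else log
    inv <- if (strategy == "systematic") identity else exp
    lo <- trans(a); hi <- trans(b)
    locs <- inv(seq(lo, hi, length.out = L))
    # guard against floating-point drift at the (always sampled) endpoints
    locs[1L] <- a; locs[L] <- b
  } else {
    grid <- seq(a, b, length.out = candidate_grid_size)
    if (L > candidate_grid_size) stop("n_locations exceeds the candidate grid")
    idx <- if (strategy == "random") {
      sample(candidate_grid_size, L, replace = FALSE)
    } else {
      mode <- sub("^pref_", "", strategy)
      w <- criticality_weights(shape, grid, mode = mode, floor_frac = weight_floor)
      sample(candidate_grid_size, L, replace = FALSE, prob = w)
    }
    locs <- sort(grid[idx])
    if (extremes_included) { locs[1L] <- a; locs[L] <- b }
  }
  locs <- sort(locs)
  if (anyDuplicated(locs)) stop("placement produced duplicate locations")
  structure(list(locations = locs, strategy_id = strategy,
                 extremes_included = extremes_included),
            class = "placement")
}

#' @exportS3Method base::print
print.placement <- function(x, ...) {
  cat(sprintf("<placement %s, L=%d%s>\n", x$strategy_id, length(x$locations),
              if (x$extremes_included) ", extremes forced" else ""))
  print(x$locations)
  invisible(x)
}
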