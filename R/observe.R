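# Observation model: replicated, heteroscedastic Gaussian draws around the
# true curve.

#' Proportional Gaussian noise model
#'
#' Observations scatter around the true response with a normal distribution
#' whose standard deviation is proportional to the absolute true response:
#' `sigma(x) = max(noise_level * |f(x)|, sd_floor)`. The floor (by default
#' `noise_level * sd_floor_fraction * range(f)`) prevents exactly-zero noise
#' where the curve crosses zero, which would otherwise pin the fit to
#' artificial anchor points. Draws are not truncated; responses are in
#' arbitrary units and may go negative.
#'
#' @param noise_level Noise magnitude as a fraction of the absolute true
#'   response (e.g. 0.2 for the close-to-real-world scenario, 1.0 for the
#'   extreme scenario).
#' @param sd_floor Absolute minimum standard deviation; `NULL` defers to
#'   `sd_floor_fraction` at draw time.
#' @param sd_floor_fraction Fraction of the shape's dense-grid response
#'   range used for the default floor.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(noise_level, sd_floor = NULL, sd_floor_fraction = 0.01) {
  stopifnot(is.numeric(noise_level), length(noise_level) == 1L)
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (!is.null(sd_floor) && sd_floor < 0) stop("sd_floor must be >= 0")
  structure(list(noise_level = noise_level, sd_floor = sd_floor,
                 sd_floor_fraction = sd_floor_fraction),
            class = "noise_model")
}

#' Draw replicated noisy samples at placed locations
#'
#' Each placed location is observed `n_replicates` times:
#' `y_ij = f(x_i) + eps_ij`, `eps_ij ~ N(0, sigma_i)` independent across
#' locations and replicates, with `sigma_i` from the [noise_model()].
#' Consumes the current RNG state; seed for reproducibility.
#'
#' @param shape A [response_shape()].
#' @param placement A placement from [place_locations()] (or a bare numeric
#'   vector of locations).
#' @param n_replicates Samples per location (>= 1).
#' @param noise A [noise_model()].
#' @return Object of class `sample_set`: data.frame with columns `x`, `y`
#'   (length `L * n_replicates`; each location repeated `n_replicates`
#'   times) and attributes `shape_id`, `strategy_id`, `n_replicates`,
#'   `noise_level`.
#' @export
draw_samples <- function(shape, placement, n_replicates, noise) {
  stopifnot(inherits(shape, "response_shape"), inherits(noise, "noise_model"),
            n_replicates >= 1L)
  locs <- if (inherits(placement, "placement")) placement$locations else as.numeric(placement)
  r <- as.integer(n_replicates)
  f <- shape$fun(locs)
  sdf <- noise$sd_floor %||% (noise$noise_level * noise$sd_floor_fraction * shape$f_range)
  sds <- pmax(noise$noise_level * abs(f), sdf)
  x <- rep(locs, each = r)
  mu <- rep(f, each = r)
  y <- mu + stats::rnorm(length(x), 0, rep(sds, each = r))
  out <- data.frame(x = x, y = y)
  attr(out, "shape_id") <- shape$shape_id
  attr(out, "strategy_id") <- if (inherits(placement, "placement")) placement$strategy_id else NA_character_
  attr(out, "n_replicates") <- r
  attr(out, "noise_level") <- noise$noise_level
  class(out) <- c("sample_set", "data.frame")
  out
}
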