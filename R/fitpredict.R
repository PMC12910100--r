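# Polynomial curve fitting, AIC-based order selection, and prediction on
# the evaluation grid.

.RSS_FLOOR <- 1e-12

# Convert coefficients of a polynomial in z = (x - c)/s back to powers of x.
.unscale_coefficients <- function(b, center, scale) {
  k <- length(b) - 1L
  out <- numeric(k + 1L)
  for (j in 0:k) {
    if (b[j + 1L] == 0) next
    # b_j * ((x - c)/s)^j expanded in powers of x
    for (m in 0:j) {
      out[m + 1L] <- out[m + 1L] +
        b[j + 1L] / scale^j * choose(j, m) * (-center)^(j - m)
    }
  }
  out
}

#' Fit a polynomial of fixed order to a sample set
#'
#' Ordinary least squares on polynomial terms of the gradient coordinate.
#' Internally the coordinate is mapped to `[-1, 1]` for conditioning;
#' coefficients are reported on the raw scale (constant term first). The
#' information criterion uses the Gaussian concentrated log-likelihood form
#' `AIC = n * log(rss / n) + 2 * (order + 2)` (parameters: order + 1
#' coefficients plus the error variance), with `rss` floored at 1e-12 so
#' perfect fits do not produce `log(0)`.
#'
#' @param samples A [draw_samples()] result, or any data.frame/list with
#'   numeric `x` and `y`.
#' @param order Polynomial degree, 1 to 4.
#' @param domain Optional [gradient_domain()] used for scaling and as the
#'   default prediction domain; inferred from the data range if missing.
#' @return Object of class `fitted_curve`: `order`, `coefficients` (raw
#'   scale), `rss`, `aic`, `n`, plus internal scaled-basis terms used by
#'   [predict_curve()].
#' @export
fit_polynomial <- function(samples, order, domain = NULL) {
  order <- as.integer(order)
  if (order < 1L || order > 4L) stop("order must be in 1..4")
  x <- samples$x; y <- samples$y
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n_distinct <- length(unique(x))
  if (n_distinct < order + 1L)
    stop(sprintf("rank error: order %d needs at least %d distinct locations, got %d",
                 order, order + 1L, n_distinct))
  if (is.null(domain)) domain <- gradient_domain(min(x), max(x))
  z <- .scale_x(x, domain)
  X <- outer(z, 0:order, `^`)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < order + 1L) stop("rank error: singular polynomial design")
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  n <- length(y)
  aic <- n * log(max(rss, .RSS_FLOOR) / n) + 2 * (order + 2)
  center <- (domain$x_min + domain$x_max) / 2
  scale <- (domain$x_max - domain$x_min) / 2
  structure(list(order = order,
                 coefficients = .unscale_coefficients(b, center, scale),
                 coef_scaled = b, domain = domain,
                 rss = rss, aic = aic, n = n, knowledge = NA_character_),
            class = "fitted_curve")
}

#' Select the prediction model for a sample set
#'
#' In the "shape unknown" scenario all feasible polynomial orders
#' (1 up to `min(max_order, distinct locations - 1)`) are fitted and the
#' fit with minimal AIC is returned, ties broken toward the lowest order.
#'
#' In the "shape known" scenario the prediction model representing the
#' known response shape is fitted. By default (`known_model =
#' "true_shape"`) this is a two-parameter calibration of the observations
#' against the true curve, `y ~ a + b * f(x)`: the shape is taken as
#' known, only level and scale are estimated, so the fit is defined for
#' any design with two distinct response levels and its accuracy does not
#' hinge on how many distinct locations were sampled. With `known_model =
#' "nominal_order"` the shape's nominal polynomial order (see
#' [nominal_order()], capped at distinct locations - 1, overridable via
#' `known_order`) is fitted instead.
#'
#' @param samples A [draw_samples()] result (or `x`/`y` data.frame).
#' @param knowledge `"unknown"` (AIC selection) or `"known"`.
#' @param shape The generating [response_shape()]; required when
#'   `knowledge = "known"`, and supplies the fitting domain.
#' @param max_order Largest candidate degree.
#' @param known_model Known-scenario model: `"true_shape"` calibration or
#'   `"nominal_order"` polynomial.
#' @param known_order Optional override of the nominal polynomial order
#'   (implies `known_model = "nominal_order"`).
#' @return A `fitted_curve` with `knowledge` recorded; a true-shape
#'   calibration has `order = 0` and `basis = "true_shape"`.
#' @export
select_model <- function(samples, knowledge = c("unknown", "known"),
                         shape = NULL, max_order = 4L,
                         known_model = c("true_shape", "nominal_order"),
                         known_order = NULL) {
  knowledge <- match.arg(knowledge)
  known_model <- match.arg(known_model)
  domain <- if (!is.null(shape)) shape$domain else NULL
  if (knowledge == "known") {
    stopifnot(inherits(shape, "response_shape"))
    if (known_model == "true_shape" && is.null(known_order)) {
      mu <- shape$fun(samples$x)
      f <- stats::lm.fit(cbind(1, mu), samples$y)
      if (f$rank < 2L)
        stop("rank error: true curve is flat across the sampled locations")
      rss <- sum(f$residuals^2)
      n <- length(samples$y)
      fit <- structure(list(
        order = 0L, basis = "true_shape",
        coefficients = unname(f$coefficients),
        coef_scaled = unname(f$coefficients),
        shape_fun = shape$fun, domain = shape$domain,
        rss = rss, aic = n * log(max(rss, .RSS_FLOOR) / n) + 2 * 3,
        n = n, knowledge = "known"), class = "fitted_curve")
      return(fit)
    }
    ord <- as.integer(known_order %||%
                        min(shape$nominal_order, length(unique(samples$x)) - 1L))
    fit <- fit_polynomial(samples, ord, domain)
  } else {
    n_distinct <- length(unique(samples$x))
    orders <- seq_len(min(max_order, n_distinct - 1L))
    if (length(orders) == 0L) stop("rank error: no feasible polynomial order")
    fits <- lapply(orders, function(k) fit_polynomial(samples, k, domain))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    fit <- fits[[which.min(aics)]]  # which.min returns the first (lowest-order) tie
  }
  fit$knowledge <- knowledge
  fit
}

#' Predict the fitted curve on the evaluation grid
#'
#' Evaluates the fitted polynomial and the true curve on `grid_size`
#' equidistant locations spanning the full gradient domain (the domain ends
#' are always in the grid, so fits from designs that never sampled the ends
#' are extrapolated — deliberately, as this is the gradient-length effect
#' under study).
#'
#' @param fit A [fit_polynomial()]/[select_model()] result.
#' @param shape The true [response_shape()].
#' @param grid_size Number of evaluation locations.
#' @return Object of class `evaluation_grid`: list with `x_eval`, `y_true`,
#'   `y_pred`.
#' @export
predict_curve <- function(fit, shape, grid_size = 1000L) {
  stopifnot(inherits(fit, "fitted_curve"), inherits(shape, "response_shape"))
  x_eval <- seq(shape$domain$x_min, shape$domain$x_max, length.out = grid_size)
  y_true <- shape$fun(x_eval)
  y_pred <- if (identical(fit$basis, "true_shape")) {
    fit$coefficients[1L] + fit$coefficients[2L] * y_true
  } else {
    z <- .scale_x(x_eval, fit$domain)
    drop(outer(z, 0:fit$order, `^`) %*% fit$coef_scaled)
  }
  structure(list(x_eval = x_eval, y_true = y_true, y_pred = y_pred),
            class = "evaluation_grid")
}

#' @export
predict.fitted_curve <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    seq(object$domain$x_min, object$domain$x_max, length.out = 100L)
  } else if (is.list(newdata)) newdata$x else as.numeric(newdata)
  if (identical(object$basis, "true_shape"))
    return(object$coefficients[1L] + object$coefficients[2L] * object$shape_fun(x))
  z <- .scale_x(x, object$domain)
  drop(outer(z, 0:object$order, `^`) %*% object$coef_scaled)
}

#' @exportS3Method base::print
print.fitted_curve <- function(x, ...) {
  cat(sprintf("<fitted_curve order %d (%s), n = %d>\n", x$order,
              if (is.na(x$knowledge)) "fixed order" else x$knowledge, x$n))
  cat("  raw coefficients:", signif(x$coefficients, 6), "\n")
  cat(sprintf("  rss = %.6g, aic = %.4f\n", x$rss, x$aic))
  invisible(x)
}
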