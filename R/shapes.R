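# Response-shape registry: the "true" curves y = f(x) that the simulated
# gradient studies try to recover.

.gradsamp_env <- new.env(parent = emptyenv())

#' Gradient domain
#'
#' The interval of the environmental driver over which responses are
#' simulated and evaluated. Units are arbitrary; the domain must be strictly
#' positive so that log-spaced placement is defined everywhere.
#'
#' @param x_min,x_max Domain endpoints, `0 < x_min < x_max`.
#' @return An object of class `gradient_domain`.
#' @examples
#' gradient_domain(1, 100)
#' @export
gradient_domain <- function(x_min = 1, x_max = 100) {
  stopifnot(is.numeric(x_min), is.numeric(x_max), length(x_min) == 1L,
            length(x_max) == 1L, is.finite(x_min), is.finite(x_max))
  if (x_min <= 0)
    stop("x_min must be > 0 (log-systematic placement requires a strictly positive domain)")
  if (x_min >= x_max) stop("x_min must be < x_max")
  structure(list(x_min = x_min, x_max = x_max), class = "gradient_domain")
}

# Built-in shape generators. Each returns list(fun, deriv) of vectorized
# closures over the domain. Constants are chosen so responses span roughly
# [0, 100] arbitrary units on the default domain [1, 100].
.builtin_shape_generators <- function() {
  list(
    linear = function(params, domain) {
      a <- params$slope %||% 1
      b <- params$intercept %||% 0
      list(fun = function(x) a * x + b, deriv = function(x) rep.int(a, length(x)))
    },
    hump = function(params, domain) {
      m <- params$center %||% (domain$x_min + domain$x_max) / 2
      h <- params$height %||% 100
      half <- (domain$x_max - domain$x_min) / 2
      k <- params$curvature %||% (h / half^2)
      list(fun = function(x) h - k * (x - m)^2,
           deriv = function(x) -2 * k * (x - m))
    },
    skewed_hump = function(params, domain) {
      # Ricker curve a*x*exp(-x/s), rescaled so the in-domain maximum is 100
      s <- params$scale %||% 20
      h <- params$height %||% 100
      xpk <- min(max(s, domain$x_min), domain$x_max)
      a <- h / (xpk * exp(-xpk / s))
      list(fun = function(x) a * x * exp(-x / s),
           deriv = function(x) a * exp(-x / s) * (1 - x / s))
    },
    saturating = function(params, domain) {
      h <- params$height %||% 100
      d <- log(domain$x_max / domain$x_min)
      list(fun = function(x) h * log(x / domain$x_min) / d,
           deriv = function(x) h / (x * d))
    },
    exponential = function(params, domain) {
      k <- params$rate %||% 0.05
      h <- params$height %||% 100
      d <- exp(k * domain$x_max) - exp(k * domain$x_min)
      list(fun = function(x) h * (exp(k * x) - exp(k * domain$x_min)) / d,
           deriv = function(x) h * k * exp(k * x) / d)
    },
    logistic = function(params, domain) {
      x0 <- params$midpoint %||% (domain$x_min + domain$x_max) / 2
      r <- params$steepness %||% 0.15
      h <- params$asymptote %||% 100
      list(fun = function(x) h / (1 + exp(-r * (x - x0))),
           deriv = function(x) {
             e <- exp(-r * (x - x0))
             h * r * e / (1 + e)^2
           })
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.shape_registry <- function() {
  if (is.null(.gradsamp_env$shapes)) .gradsamp_env$shapes <- .builtin_shape_generators()
  .gradsamp_env$shapes
}

#' List available response-shape ids
#' @return Character vector of shape ids usable with [response_shape()].
#' @export
list_shapes <- function() names(.shape_registry())

#' Register a custom response shape
#'
#' Adds (or replaces) a shape in the registry. The generator receives the
#' parameter list and the domain and must return `list(fun, deriv)` of
#' vectorized functions; `deriv` is the analytic derivative of `fun`.
#'
#' @param shape_id Character id for the new shape.
#' @param generator `function(params, domain)` returning `list(fun, deriv)`.
#' @return `shape_id`, invisibly.
#' @export
register_shape <- function(shape_id, generator) {
  stopifnot(is.character(shape_id), length(shape_id) == 1L, is.function(generator))
  reg <- .shape_registry()
  reg[[shape_id]] <- generator
  .gradsamp_env$shapes <- reg
  invisible(shape_id)
}

#' Construct a response shape
#'
#' A response shape is a deterministic true curve `y = f(x)` on a gradient
#' domain together with its analytic derivative. The constructor caches the
#' curve on a dense grid (min, max, range) for extremeness-based criticality
#' and determines the shape's nominal polynomial order for the
#' "shape known a priori" fitting scenario.
#'
#' @param shape_id One of [list_shapes()] (by default `linear`, `hump`,
#'   `skewed_hump`, `saturating`, `exponential`, `logistic`) or a custom
#'   registered id.
#' @param params Named list of shape-specific constants overriding defaults.
#' @param domain A [gradient_domain()].
#' @param dense_n Grid size used for the cached curve summary.
#' @return An object of class `response_shape` with elements `shape_id`,
#'   `fun`, `deriv`, `domain`, `f_min`, `f_max`, `f_range`, `nominal_order`.
#' @examples
#' sh <- response_shape("logistic")
#' evaluate_shape(sh, c(1, 50.5, 100))
#' @export
response_shape <- function(shape_id, params = list(), domain = gradient_domain(),
                           dense_n = 1000L) {
  reg <- .shape_registry()
  if (!shape_id %in% names(reg))
    stop(sprintf("unknown shape '%s'; valid shapes: %s", shape_id,
                 paste(names(reg), collapse = ", ")))
  stopifnot(inherits(domain, "gradient_domain"), is.list(params))
  fd <- reg[[shape_id]](params, domain)
  xg <- seq(domain$x_min, domain$x_max, length.out = dense_n)
  fg <- fd$fun(xg)
  if (!all(is.finite(fg)))
    stop(sprintf("shape '%s' is not finite over the whole domain", shape_id))
  obj <- structure(list(
    shape_id = shape_id, params = params, fun = fd$fun, deriv = fd$deriv,
    domain = domain, dense_x = xg, dense_f = fg,
    f_min = min(fg), f_max = max(fg), f_range = max(fg) - min(fg)
  ), class = "response_shape")
  obj$nominal_order <- nominal_order(obj)
  obj
}

.check_in_domain <- function(x, domain) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("x must be finite numeric")
  eps <- 1e-9 * (domain$x_max - domain$x_min)
  if (any(x < domain$x_min - eps) || any(x > domain$x_max + eps))
    stop(sprintf("x outside the gradient domain [%g, %g]", domain$x_min, domain$x_max))
  invisible(TRUE)
}

#' Evaluate the true response curve
#'
#' @param shape A [response_shape()].
#' @param x Gradient coordinate(s) within the domain.
#' @return `f(x)`, noiseless and deterministic.
#' @export
evaluate_shape <- function(shape, x) {
  stopifnot(inherits(shape, "response_shape"))
  .check_in_domain(x, shape$domain)
  shape$fun(x)
}

#' Evaluate the analytic slope of the true response curve
#'
#' The local slope `f'(x)` drives the slope-based criticality used by
#' preferential placement.
#'
#' @inheritParams evaluate_shape
#' @return `f'(x)`.
#' @export
shape_derivative <- function(shape, x) {
  stopifnot(inherits(shape, "response_shape"))
  .check_in_domain(x, shape$domain)
  shape$deriv(x)
}

#' Nominal polynomial order of a shape
#'
#' The lowest polynomial degree whose least-squares fit to the noiseless
#' dense curve reaches a multiple R-squared of at least `threshold`; if no
#' degree up to `max_order` does, `max_order` is used. This is the degree
#' fitted in the "response shape known a priori" scenario (the linear shape
#' maps to degree 1 and the centered hump to degree 2 by construction).
#'
#' @param shape A [response_shape()].
#' @param max_order Largest degree considered.
#' @param threshold R-squared required to call a degree adequate.
#' @return Integer degree in `1:max_order`.
#' @export
nominal_order <- function(shape, max_order = 4L, threshold = 0.995) {
  z <- .scale_x(shape$dense_x, shape$domain)
  y <- shape$dense_f
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(1L)  # constant curve: any degree is equivalent
  X <- outer(z, 0:max_order, `^`)  # columns z^0 .. z^max_order
  for (k in seq_len(max_order)) {
    fit <- stats::lm.fit(X[, seq_len(k + 1L), drop = FALSE], y)
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 >= threshold) return(as.integer(k))
  }
  as.integer(max_order)
}

# map x to [-1, 1] for numerically stable polynomial bases
.scale_x <- function(x, domain) {
  (x - (domain$x_min + domain$x_max) / 2) / ((domain$x_max - domain$x_min) / 2)
}

#' @exportS3Method base::print
print.response_shape <- function(x, ...) {
  cat(sprintf("<response_shape '%s' on [%g, %g]>\n", x$shape_id,
              x$domain$x_min, x$domain$x_max))
  cat(sprintf("  response span: [%.3g, %.3g]; nominal polynomial order: %d\n",
              x$f_min, x$f_max, x$nominal_order))
  invisible(x)
}

#' @export
plot.response_shape <- function(x, n = 400L, ...) {
  xs <- seq(x$domain$x_min, x$domain$x_max, length.out = n)
  plot(xs, x$fun(xs), type = "l", xlab = "gradient (arbitrary units)",
       ylab = "response (arbitrary units)", main = x$shape_id, ...)
  invisible(x)
}
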