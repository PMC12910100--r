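# The three prediction-accuracy metrics compared by the framework.

.as_pred_true <- function(y_pred, y_true) {
  if (inherits(y_pred, "evaluation_grid")) {
    list(p = y_pred$y_pred, t = y_pred$y_true)
  } else {
    stopifnot(length(y_pred) == length(y_true))
    list(p = as.numeric(y_pred), t = as.numeric(y_true))
  }
}

#' Multiple R-squared between predicted and true responses
#'
#' Squared Pearson correlation between predictions and truth over the
#' evaluation grid — the R-squared of a simple regression of one on the
#' other, in either direction. Affine-invariant: it measures only how
#' tightly predictions and truth covary, not whether they match. A constant
#' prediction (or truth) has undefined correlation and scores 0 by
#' convention.
#'
#' @param y_pred Predicted responses, or an `evaluation_grid`.
#' @param y_true True responses (ignored if `y_pred` is a grid).
#' @return Accuracy in `[0, 1]`, 1 = predictions collinear with truth.
#' @export
multiple_r2 <- function(y_pred, y_true = NULL) {
  g <- .as_pred_true(y_pred, y_true)
  sp <- sum((g$p - mean(g$p))^2)
  st <- sum((g$t - mean(g$t))^2)
  if (sp <= 0 || st <= 0) return(0)
  (sum((g$p - mean(g$p)) * (g$t - mean(g$t)))^2) / (sp * st)
}

#' Prediction success of the fixed identity model
#'
#' Coefficient of determination of the regression of predicted on true
#' responses forced through zero with slope one (Chalcraft-style):
#' `PS = 1 - sum((pred - true)^2) / sum((true - mean(true))^2)`. Unlike
#' [multiple_r2()] this penalizes bias and scale error — `PS = 1` iff
#' predictions match truth exactly — and can go negative when predictions
#' are worse than predicting the true mean everywhere. With
#' `normalizer = "true_raw"` the denominator is the raw sum of squares of
#' the true values instead of centered deviations (sensitivity variant).
#'
#' @inheritParams multiple_r2
#' @param normalizer `"true_centered"` (default) or `"true_raw"`.
#' @return Accuracy `<= 1`; `NA` if the true curve is constant.
#' @export
chalcraft_ps <- function(y_pred, y_true = NULL,
                         normalizer = c("true_centered", "true_raw")) {
  normalizer <- match.arg(normalizer)
  g <- .as_pred_true(y_pred, y_true)
  denom <- if (normalizer == "true_centered") sum((g$t - mean(g$t))^2) else sum(g$t^2)
  if (denom <= 0) return(NA_real_)
  1 - sum((g$p - g$t)^2) / denom
}

#' Negative root-mean-square error
#'
#' `-sqrt(mean((pred - true)^2))`; negated so that, like the other two
#' metrics, larger is better (0 is perfect). Unlike the R-squared-type
#' metrics it is on the response scale and responds linearly to the noise
#' magnitude.
#'
#' @inheritParams multiple_r2
#' @return Accuracy `<= 0`.
#' @export
neg_rmse <- function(y_pred, y_true = NULL) {
  g <- .as_pred_true(y_pred, y_true)
  -sqrt(mean((g$p - g$t)^2))
}

#' Score an evaluation grid with all three accuracy metrics
#'
#' @param grid An `evaluation_grid` from [predict_curve()].
#' @param ps_normalizer Passed to [chalcraft_ps()].
#' @return Named numeric vector `r2_multiple`, `chalcraft_ps`, `neg_rmse`.
#' @export
score_grid <- function(grid, ps_normalizer = "true_centered") {
  c(r2_multiple = multiple_r2(grid),
    chalcraft_ps = chalcraft_ps(grid, normalizer = ps_normalizer),
    neg_rmse = neg_rmse(grid))
}
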