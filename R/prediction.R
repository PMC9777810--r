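#' Predict the initial-rate constant at a new operating condition
#'
#' Evaluates a fitted response-surface model at a coded condition
#' `x0 = (x1, x2)` and attaches the confidence interval
#' `a_pred +/- t(alpha/2, df) * sqrt(sigma2 * x0' (X'X)^-1 x0)`, where the
#' quadratic form is the leverage of the new condition under the fitted
#' model. With the default convention df = n - p (p retained terms
#' including the intercept); `convention = "paper"` uses n - p - 1.
#'
#' Conditions outside the design's axial radius in any coordinate are
#' extrapolations and trigger a warning, not an error.
#'
#' @param model an [fit_polynomial()] / [reduce_model()] result.
#' @param x0 coded condition, length-2 numeric `(x1, x2)`.
#' @param confidence confidence level (default 0.95).
#' @param convention degrees-of-freedom convention, `"standard"` or
#'   `"paper"`.
#' @return An object of class `prediction_result`: list with `x0`,
#'   `a_pred`, `se_pred`, `ci_low`, `ci_high`, `confidence`, `df`.
#' @examples
#' m <- reduce_model(milk_study_design(), milk_kinetic_constants("Alcalase")$a)
#' predict_a(m, c(-0.5, 0))
#' @export
predict_a <- function(model, x0, confidence = 0.95,
                      convention = c("standard", "paper")) {
  stopifnot(inherits(model, "rsm_model"))
  convention <- match.arg(convention)
  x0 <- as.numeric(x0)
  if (length(x0) != 2 || any(!is.finite(x0))) {
    stop("`x0` must be a finite coded pair (x1, x2)", call. = FALSE)
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("`confidence` must be in (0, 1)", call. = FALSE)
  }
  if (is.finite(model$axial) && any(abs(x0) > model$axial + 1e-9)) {
    warning(sprintf(
      "condition (%.3g, %.3g) lies outside the design's axial radius %.4g: extrapolating",
      x0[1], x0[2], model$axial))
  }
  x0row <- rsm_model_matrix(matrix(x0, nrow = 1,
                                   dimnames = list(NULL, c("x1", "x2"))),
                            model$terms)
  a_pred <- unname(drop(x0row %*% model$coefficients))
  lev <- unname(drop(x0row %*% model$dispersion %*% t(x0row)))
  df <- switch(convention,
               standard = model$df_residual,
               paper = model$df_residual - 1)
  # the convention fixes the error degrees of freedom everywhere it
  # appears: both the residual-variance estimate SSE/df and the t quantile
  sse <- model$residual_variance * model$df_residual
  se_pred <- sqrt(sse / df * lev)
  tq <- stats::qt(1 - (1 - confidence) / 2, df)
  structure(
    list(x0 = x0, a_pred = a_pred, se_pred = se_pred,
         ci_low = a_pred - tq * se_pred, ci_high = a_pred + tq * se_pred,
         confidence = confidence, df = df),
    class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "Predicted a at (x1, x2) = (%.3g, %.3g): %.4g mM/min (se %.3g)\n",
    x$x0[1], x$x0[2], x$a_pred, x$se_pred))
  cat(sprintf("  %g%% CI: [%.4g, %.4g], df = %d\n",
              100 * x$confidence, x$ci_low, x$ci_high, x$df))
  invisible(x)
}

#' Predicted hydrolysis curve with confidence band
#'
#' Propagates the interval on the initial-rate constant through the
#' logarithmic model with the attenuation constant held fixed. Because
#' the model is monotone increasing in `a`, evaluating it at the interval
#' endpoints gives the exact band for the curve; the band therefore
#' reflects only the uncertainty in `a` (b is treated as a fixed
#' constant). The degree-of-hydrolysis series applies the titration
#' stoichiometry to each band edge.
#'
#' @param a_result a [predict_a()] result.
#' @param b_fixed fixed attenuation constant, 1/mM (> 0); see [fixed_b()].
#' @param times time grid in minutes starting at 0.
#' @param config an [assay_config()] for the DH conversion.
#' @return An object of class `predicted_curve`: data.frame with columns
#'   `time`, `p_low`, `p_mid`, `p_high`, `dh_low`, `dh_mid`, `dh_high`.
#' @examples
#' m <- reduce_model(milk_study_design(), milk_kinetic_constants("Alcalase")$a)
#' pc <- predict_curve(predict_a(m, c(0, -1)), b_fixed = 0.0410,
#'                     times = seq(0, 60, 5))
#' pc[pc$time == 60, ]
#' @export
predict_curve <- function(a_result, b_fixed, times = seq(0, 60, by = 1),
                          config = assay_config()) {
  stopifnot(inherits(a_result, "prediction_result"))
  if (!is.finite(b_fixed) || b_fixed <= 0) {
    stop("`b_fixed` must be strictly positive", call. = FALSE)
  }
  if (times[1] != 0) stop("`times` must start at 0", call. = FALSE)
  lo <- a_result$ci_low
  if (lo < 0) {
    warning("lower confidence limit for a is negative; clamping to 0")
    lo <- 0
  }
  p_mid <- log_model(a_result$a_pred, b_fixed, times)
  p_low <- log1p(lo * b_fixed * times) / b_fixed  # a = 0 allowed here
  p_high <- log_model(a_result$ci_high, b_fixed, times)
  structure(
    data.frame(time = times,
               p_low = p_low, p_mid = p_mid, p_high = p_high,
               dh_low = alpha_nh_to_dh(p_low, config),
               dh_mid = alpha_nh_to_dh(p_mid, config),
               dh_high = alpha_nh_to_dh(p_high, config)),
    class = c("predicted_curve", "data.frame"))
}

#' @export
print.predicted_curve <- function(x, ...) {
  tend <- which.max(x$time)
  cat(sprintf(
    "Predicted hydrolysis curve: %d points to t = %.4g min\n",
    nrow(x), x$time[tend]))
  cat(sprintf("  final DH %.3g%% (band %.3g-%.3g%%)\n",
              x$dh_mid[tend], x$dh_low[tend], x$dh_high[tend]))
  invisible(x)
}

#' Relative percent error of a prediction
#'
#' `100 * |predicted - experimental| / experimental`.
#'
#' @param predicted,experimental numeric, vectorized; `experimental`
#'   must be nonzero.
#' @return percent error(s).
#' @export
percent_error <- function(predicted, experimental) {
  if (any(experimental == 0)) {
    stop("percent error is undefined for a zero experimental value",
         call. = FALSE)
  }
  100 * abs(predicted - experimental) / abs(experimental)
}

#' Squared correlation between predicted and experimental values
#'
#' The squared Pearson correlation. Note this is sign-blind: a perfectly
#' anti-correlated pair also scores 1.
#'
#' @param predicted,experimental equal-length numeric vectors (>= 2
#'   points) with nonzero variance.
#' @return R^2 in \[0, 1\].
#' @export
validation_correlation <- function(predicted, experimental) {
  if (length(predicted) != length(experimental) || length(predicted) < 2) {
    stop("need two equal-length vectors of at least 2 points", call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(predicted, experimental)^2
}
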