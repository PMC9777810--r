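#' Coded-variable definition for a designed factor
#'
#' Maps between natural units and dimensionless coded units:
#' `coded = (natural - center) / step`.
#'
#' @param name factor label, e.g. `"T"` (temperature, deg C) or `"E"`
#'   (protease dose, mAU).
#' @param center natural value at coded 0.
#' @param step natural units per coded unit (> 0).
#' @param axial coded axial distance of the design (>= 1), `sqrt(2)` for a
#'   two-factor circumscribed design.
#' @return An object of class `variable_coding`.
#' @examples
#' tc <- variable_coding("T", center = 55, step = 5)
#' decode(tc, c(-sqrt(2), -1, 0, 1, sqrt(2)))
#' @export
variable_coding <- function(name, center, step, axial = sqrt(2)) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (!is.finite(axial) || axial < 1) stop("`axial` must be >= 1", call. = FALSE)
  structure(list(name = name, center = center, step = step, axial = axial),
            class = "variable_coding")
}

#' @rdname variable_coding
#' @param coding a `variable_coding`.
#' @param x coded value(s).
#' @export
decode <- function(coding, x) {
  stopifnot(inherits(coding, "variable_coding"))
  coding$center + x * coding$step
}

#' @rdname variable_coding
#' @param natural natural-unit value(s).
#' @export
encode <- function(coding, natural) {
  stopifnot(inherits(coding, "variable_coding"))
  (natural - coding$center) / coding$step
}

#' @export
print.variable_coding <- function(x, ...) {
  cat(sprintf("Coded variable %s: center %.4g, step %.4g, axial %.4g\n",
              x$name, x$center, x$step, x$axial))
  invisible(x)
}

#' Central composite circumscribed design in coded units
#'
#' Emits the full-factorial corners at (+/-1, +/-1), axial points at
#' (+/-axial, 0) and (0, +/-axial), and `n_center` replicated center
#' points, for two coded factors.
#'
#' @param codings list of two [variable_coding()]s (x1 then x2); their
#'   axial distances must agree.
#' @param n_center number of center replicates (>= 1).
#' @return An object of class `ccc_design`: a list with `points` (matrix
#'   with columns `x1`, `x2`), `n_center`, `axial` and `codings`.
#' @examples
#' dsn <- build_ccc(list(variable_coding("T", 55, 5),
#'                       variable_coding("E", 125, 75)), n_center = 2)
#' dsn
#' @export
build_ccc <- function(codings = list(variable_coding("T", 55, 5),
                                     variable_coding("E", 125, 75)),
                      n_center = 2) {
  stopifnot(length(codings) == 2,
            all(vapply(codings, inherits, TRUE, "variable_coding")))
  n_center <- as.integer(n_center)
  if (n_center < 1) stop("`n_center` must be >= 1", call. = FALSE)
  ax <- codings[[1]]$axial
  if (abs(ax - codings[[2]]$axial) > 1e-12) {
    stop("the two codings declare different axial distances", call. = FALSE)
  }
  pts <- rbind(
    cbind(x1 = c(-1, 1, -1, 1), x2 = c(-1, -1, 1, 1)),
    cbind(x1 = c(-ax, ax, 0, 0), x2 = c(0, 0, -ax, ax)),
    cbind(x1 = rep(0, n_center), x2 = rep(0, n_center))
  )
  rownames(pts) <- NULL
  structure(list(points = pts, n_center = n_center, axial = ax,
                 codings = codings),
            class = "ccc_design")
}

#' @export
print.ccc_design <- function(x, ...) {
  cat(sprintf(
    "Central composite circumscribed design: %d runs (4 factorial, 4 axial at +/-%.4g, %d center)\n",
    nrow(x$points), x$axial, x$n_center))
  for (cd in x$codings) {
    cat(sprintf("  %s: %s\n", cd$name,
                paste(signif(decode(cd, c(-x$axial, -1, 0, 1, x$axial)), 4),
                      collapse = " / ")))
  }
  invisible(x)
}

# Canonical second-order term labels for two coded factors.
rsm_full_terms <- function() {
  c("(Intercept)", "x1", "x2", "x1^2", "x2^2", "x1:x2")
}

# Model matrix over the coded points for a term subset. `points` may be a
# ccc_design, a matrix, or a data.frame with columns x1, x2.
rsm_model_matrix <- function(points, terms) {
  if (inherits(points, "ccc_design")) points <- points$points
  points <- as.matrix(points)
  if (is.null(colnames(points))) colnames(points) <- c("x1", "x2")
  x1 <- points[, "x1"]; x2 <- points[, "x2"]
  cols <- list("(Intercept)" = rep(1, length(x1)),
               "x1" = x1, "x2" = x2,
               "x1^2" = x1^2, "x2^2" = x2^2, "x1:x2" = x1 * x2)
  bad <- setdiff(terms, names(cols))
  if (length(bad)) {
    stop("unknown polynomial term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X <- do.call(cbind, cols[terms])
  colnames(X) <- terms
  X
}

#' Fit a second-order polynomial response-surface model
#'
#' Ordinary least squares of a response on a subset of the coded
#' second-order terms \{1, x1, x2, x1^2, x2^2, x1:x2\}. Per-coefficient
#' standard errors come from `sigma2 * diag((X'X)^-1)`, t statistics are
#' `beta/se` and two-sided p-values use Student's t with `n - p` degrees
#' of freedom (p = number of terms including the intercept).
#'
#' @param design a [build_ccc()] design, or a matrix/data.frame of coded
#'   points with columns `x1`, `x2`.
#' @param response numeric response, one value per design row.
#' @param terms character subset of
#'   `c("(Intercept)", "x1", "x2", "x1^2", "x2^2", "x1:x2")`; must include
#'   the intercept. Defaults to the full second-order set.
#' @return An object of class `rsm_model`.
#' @examples
#' dsn <- build_ccc(n_center = 2)
#' a_alc <- milk_kinetic_constants("Alcalase")$a
#' fit_polynomial(milk_study_design(), a_alc,
#'                terms = c("(Intercept)", "x1", "x2", "x1:x2"))
#' @export
fit_polynomial <- function(design, response, terms = rsm_full_terms()) {
  if (!"(Intercept)" %in% terms) {
    stop("`terms` must include \"(Intercept)\"", call. = FALSE)
  }
  bad <- setdiff(terms, rsm_full_terms())
  if (length(bad)) {
    stop("unknown polynomial term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # canonical term order
  terms <- intersect(rsm_full_terms(), terms)
  X <- rsm_model_matrix(design, terms)
  y <- as.numeric(response)
  if (nrow(X) != length(y)) {
    stop("response length (", length(y), ") does not match design rows (",
         nrow(X), ")", call. = FALSE)
  }
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("more terms than observations", call. = FALSE)

  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) {
    sv <- svd(XtX)
    null_dir <- abs(sv$v[, p])
    stop("singular design: collinear terms involving ",
         paste(colnames(X)[null_dir > 1e-6], collapse = ", "), call. = FALSE)
  }
  C <- solve(XtX)
  beta <- drop(C %*% crossprod(X, y))
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / (n - p)
  se <- sqrt(sigma2 * diag(C))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)

  axial <- if (inherits(design, "ccc_design")) design$axial else NA_real_
  structure(
    list(terms = terms, coefficients = beta, se = se,
         t_values = tval, p_values = pval,
         r_squared = r2, adj_r_squared = adj_r2,
         dispersion = C, residual_variance = sigma2,
         n = n, df_residual = n - p,
         X = X, y = y, fitted = fitted, residuals = resid,
         axial = axial),
    class = "rsm_model"
  )
}

#' @export
print.rsm_model <- function(x, digits = 4, ...) {
  cat("Polynomial response-surface model (coded units)\n")
  tab <- data.frame(
    coefficient = signif(x$coefficients, digits),
    se = signif(x$se, digits),
    t = signif(x$t_values, digits),
    p = format(x$p_values, digits = 3, scientific = TRUE))
  print(tab)
  cat(sprintf("R^2 = %.4f, adj. R^2 = %.4f, sigma^2 = %.4g (df = %d)\n",
              x$r_squared, x$adj_r_squared, x$residual_variance,
              x$df_residual))
  invisible(x)
}

#' @export
coef.rsm_model <- function(object, ...) object$coefficients

#' Backward elimination of non-significant polynomial terms
#'
#' Reduces the full second-order model (or a supplied term set) by
#' removing non-intercept terms whose t-test p-value exceeds `alpha`.
#' Two strategies are available. `"single"` (the default) fits the full
#' model once and drops every non-significant term together, then refits
#' — the classic reduce-the-polynomial step of applied response-surface
#' work. `"iterative"` removes the single worst term and refits, looping
#' until every remaining term is significant; it is more conservative
#' when terms are correlated but can retain borderline curvature terms
#' that the single-pass strategy discards. On this package's orthogonal
#' designs the two mostly agree; they can differ for terms whose p-value
#' sits near `alpha`. The intercept is always retained; the worst case
#' is an intercept-only model.
#'
#' @inheritParams fit_polynomial
#' @param alpha per-term significance threshold (default 0.05).
#' @param method `"single"` (one pass, default) or `"iterative"`
#'   (worst-term-at-a-time).
#' @return An `rsm_model` over the retained terms.
#' @export
reduce_model <- function(design, response, alpha = 0.05,
                         terms = rsm_full_terms(),
                         method = c("single", "iterative")) {
  stopifnot(alpha > 0, alpha < 1)
  method <- match.arg(method)
  model <- fit_polynomial(design, response, terms)
  if (method == "single") {
    nonint <- setdiff(model$terms, "(Intercept)")
    keep <- nonint[model$p_values[nonint] <= alpha]
    if (length(keep) == length(nonint)) return(model)
    return(fit_polynomial(design, response, c("(Intercept)", keep)))
  }
  repeat {
    drop_candidates <- setdiff(model$terms, "(Intercept)")
    if (!length(drop_candidates)) return(model)
    pv <- model$p_values[drop_candidates]
    if (max(pv) <= alpha) return(model)
    worst <- drop_candidates[which.max(pv)]
    model <- fit_polynomial(design, response, setdiff(model$terms, worst))
  }
}

#' Analysis of variance for a response-surface model
#'
#' Decomposes `SS_total = SS_regression + SS_error` about the response
#' mean. Two degree-of-freedom conventions are available: `"standard"`
#' counts `p - 1` regression df and `n - p` error df (p = number of terms
#' including the intercept); `"paper"` counts the intercept among the
#' regression df (`p` regression, `n - p - 1` error), a convention found
#' in some applied response-surface reports. The F statistic is
#' `MS_regression / MS_error` under the chosen convention.
#'
#' @param model an [fit_polynomial()] / [reduce_model()] result.
#' @param convention `"standard"` (default) or `"paper"`.
#' @return An object of class `rsm_anova`: data.frame with rows
#'   Regression, Error, Total and columns `df`, `ss`, `ms`, `f`, `p`.
#' @export
anova_table <- function(model, convention = c("standard", "paper")) {
  stopifnot(inherits(model, "rsm_model"))
  convention <- match.arg(convention)
  y <- model$y
  ybar <- mean(y)
  ss_reg <- sum((model$fitted - ybar)^2)
  ss_err <- sum(model$residuals^2)
  ss_tot <- sum((y - ybar)^2)
  n <- model$n
  p <- length(model$terms)
  df <- switch(convention,
               standard = c(p - 1, n - p, n - 1),
               paper = c(p, n - p - 1, n - 1))
  # an intercept-only model has no regression df under the standard
  # convention; its F test is undefined
  ms <- c(if (df[1] > 0) ss_reg / df[1] else NA, ss_err / df[2], NA)
  f <- ms[1] / ms[2]
  pval <- if (df[1] > 0) {
    stats::pf(f, df[1], df[2], lower.tail = FALSE)
  } else NA_real_
  out <- data.frame(
    source = c("Regression", "Error", "Total"),
    df = df, ss = c(ss_reg, ss_err, ss_tot), ms = ms,
    f = c(f, NA, NA), p = c(pval, NA, NA))
  structure(out, class = c("rsm_anova", "data.frame"),
            convention = convention)
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("ANOVA (%s df convention)\n", attr(x, "convention")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Fixed attenuation constant for curve prediction
#'
#' When the attenuation constant b is only weakly correlated with the
#' operating conditions, hydrolysis curves are predicted with b held at
#' its value at the design center. Given a reduced b-model this is the
#' model's prediction at the center (all coded terms zero, i.e. the
#' intercept); given a raw vector of per-run b values it is their mean,
#' which coincides with the model value when no pure-quadratic term is
#' retained on an orthogonal design.
#'
#' @param b either an `rsm_model` fitted to b values or a numeric vector
#'   of b values.
#' @return fixed b, 1/mM.
#' @export
fixed_b <- function(b) {
  if (inherits(b, "rsm_model")) {
    return(unname(b$coefficients["(Intercept)"]))
  }
  if (is.numeric(b)) return(mean(b))
  stop("`b` must be an rsm_model or a numeric vector", call. = FALSE)
}
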