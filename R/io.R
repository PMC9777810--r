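# CSV and configuration I/O. Formats are deliberately plain: comma
# separation, header row, '.' decimal regardless of locale.

read_numeric_csv <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  if (nrow(raw) == 0) {
    stop("no data rows in ", path, call. = FALSE)
  }
  missing <- setdiff(required_cols, names(raw))
  if (length(missing)) {
    stop("missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  for (cl in required_cols) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        hint <- if (any(grepl(",", v[bad]))) {
          " (comma decimals are not accepted; use '.')"
        } else ""
        stop(sprintf("non-numeric value '%s' in column '%s' at data line %d of %s%s",
                     v[bad[1]], cl, bad[1], path, hint), call. = FALSE)
      }
      raw[[cl]] <- num
    }
  }
  raw[required_cols]
}

#' Read and write hydrolysis curves and titration traces
#'
#' `read_curve()` expects columns `time,alpha_nh_mM`; `read_trace()`
#' expects `time,volume` (cumulative mL). `write_curve()` writes
#' `time,alpha_nh_mM,dh_percent` at full precision. Numbers use the '.'
#' decimal; malformed values are rejected with their line number.
#'
#' @param path CSV file path.
#' @return `read_curve()`: a [hydrolysis_curve()]; `read_trace()`: a
#'   data.frame `time`, `volume`.
#' @export
read_curve <- function(path) {
  d <- read_numeric_csv(path, c("time", "alpha_nh_mM"))
  hydrolysis_curve(d$time, d$alpha_nh_mM)
}

#' @rdname read_curve
#' @export
read_trace <- function(path) {
  read_numeric_csv(path, c("time", "volume"))
}

#' @rdname read_curve
#' @param curve a [hydrolysis_curve()].
#' @param config an [assay_config()] for the DH column.
#' @export
write_curve <- function(curve, path, config = assay_config()) {
  stopifnot(inherits(curve, "hydrolysis_curve"))
  out <- data.frame(
    time = format(curve$time, digits = 17, trim = TRUE, scientific = FALSE),
    alpha_nh_mM = format(curve$product, digits = 17, trim = TRUE),
    dh_percent = format(alpha_nh_to_dh(curve$product, config),
                        digits = 17, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read assay constants from a flat key=value file
#'
#' Accepts lines `key = value` (or `key: value`), `#` comments and blank
#' lines. Recognized keys: `normality`, `alpha` (or `dissociation`),
#' `reaction_volume_l`, `h_total`, `protein_mass_g`; missing keys keep the
#' [assay_config()] defaults.
#'
#' @param path configuration file path.
#' @return An [assay_config()].
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) {
      stop("cannot parse configuration line: '", ln, "'", call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(m[3]))
    if (is.na(val)) {
      stop("non-numeric value for '", m[2], "': ", m[3], call. = FALSE)
    }
    kv[[m[2]]] <- val
  }
  if (!is.null(kv$alpha) && is.null(kv$dissociation)) {
    kv$dissociation <- kv$alpha
  }
  defaults <- formals(assay_config)
  args <- lapply(names(defaults), function(nm) {
    if (!is.null(kv[[nm]])) kv[[nm]] else eval(defaults[[nm]])
  })
  names(args) <- names(defaults)
  do.call(assay_config, args)
}

#' Run the full two-level modeling study
#'
#' Executes the complete pipeline on a set of per-run inputs over a
#' design: fit the logarithmic model to every curve, regress the fitted
#' constants a and b on the coded conditions with backward elimination,
#' derive the fixed attenuation constant, and (optionally) predict a and
#' the 60-min degree of hydrolysis at validation conditions.
#'
#' @param curves list, one element per design row: a
#'   [hydrolysis_curve()], a titration data.frame (`time`, `volume`), or
#'   a CSV path (column names decide the reader).
#' @param design a [build_ccc()] design with as many rows as `curves`.
#' @param config an [assay_config()].
#' @param alpha significance threshold for [reduce_model()].
#' @param convention ANOVA/df convention, `"standard"` or `"paper"`.
#' @param predict_at optional matrix/data.frame of coded conditions
#'   (columns `x1`, `x2`) at which to predict a and DH at `t_end`.
#' @param t_end prediction horizon in minutes (default 60).
#' @param label study label used in reports.
#' @return An object of class `study_bundle`: list with `fits`,
#'   `constants` (data.frame of per-run a, b), `a_model`, `b_model`,
#'   `b_fixed`, `anova_a`, `anova_b`, `predictions`, `failed` (indices of
#'   runs whose fit failed), plus the inputs.
#' @examples
#' sc <- simulation_scenario(
#'   surface = c("(Intercept)" = 9.69, x1 = 4.56, x2 = 4.88, "x1:x2" = 2.82),
#'   b_true = 0.041, sample_interval = 10, seed = 7)
#' st <- simulate_design_study(sc)
#' run_study(st$traces, design = build_ccc())
#' @export
run_study <- function(curves, design = build_ccc(),
                      config = assay_config(), alpha = 0.05,
                      convention = c("standard", "paper"),
                      predict_at = NULL, t_end = 60, label = "study") {
  convention <- match.arg(convention)
  if (!length(curves)) stop("empty curve list", call. = FALSE)
  if (length(curves) != nrow(design$points)) {
    stop(sprintf("%d curves for %d design rows", length(curves),
                 nrow(design$points)), call. = FALSE)
  }

  as_curve <- function(x) {
    if (inherits(x, "hydrolysis_curve")) return(x)
    if (is.character(x)) {
      hdr <- names(utils::read.csv(x, nrows = 1))
      x <- if ("volume" %in% hdr) read_trace(x) else read_curve(x)
    }
    if (inherits(x, "hydrolysis_curve")) return(x)
    if (is.data.frame(x) && all(c("time", "volume") %in% names(x))) {
      return(trace_to_curve(x, config))
    }
    if (is.data.frame(x) && all(c("time", "product") %in% names(x))) {
      return(hydrolysis_curve(x$time, x$product))
    }
    stop("cannot interpret a curve input of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }

  fits <- vector("list", length(curves))
  failed <- integer(0)
  for (i in seq_along(curves)) {
    fits[[i]] <- tryCatch(fit_log_model(as_curve(curves[[i]])),
                          error = function(e) e)
    if (inherits(fits[[i]], "error")) failed <- c(failed, i)
  }
  if (length(failed) == length(curves)) {
    stop("every per-curve fit failed; first error: ",
         conditionMessage(fits[[failed[1]]]), call. = FALSE)
  }

  ok <- setdiff(seq_along(fits), failed)
  constants <- data.frame(
    run = ok,
    x1 = design$points[ok, "x1"], x2 = design$points[ok, "x2"],
    a = vapply(fits[ok], `[[`, 0, "a"),
    b = vapply(fits[ok], `[[`, 0, "b"),
    r_squared = vapply(fits[ok], `[[`, 0, "r_squared"))

  sub_design <- design
  sub_design$points <- design$points[ok, , drop = FALSE]
  a_model <- reduce_model(sub_design, constants$a, alpha = alpha)
  b_model <- reduce_model(sub_design, constants$b, alpha = alpha)
  b_fix <- fixed_b(b_model)

  predictions <- NULL
  if (!is.null(predict_at)) {
    predict_at <- as.matrix(predict_at)
    predictions <- do.call(rbind, lapply(seq_len(nrow(predict_at)), function(i) {
      pr <- predict_a(a_model, predict_at[i, ], convention = convention)
      pc <- predict_curve(pr, b_fix, times = c(0, t_end), config = config)
      data.frame(x1 = pr$x0[1], x2 = pr$x0[2],
                 a_pred = pr$a_pred, se_pred = pr$se_pred,
                 ci_low = pr$ci_low, ci_high = pr$ci_high,
                 dh_pred = pc$dh_mid[2],
                 dh_low = pc$dh_low[2], dh_high = pc$dh_high[2])
    }))
  }

  structure(
    list(label = label, fits = fits, failed = failed,
         constants = constants,
         a_model = a_model, b_model = b_model, b_fixed = b_fix,
         anova_a = anova_table(a_model, convention),
         anova_b = anova_table(b_model, convention),
         predictions = predictions,
         design = design, config = config,
         alpha = alpha, convention = convention),
    class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("Two-level hydrolysis study '%s': %d runs (%d failed)\n",
              x$label, length(x$fits), length(x$failed)))
  cat("\nReduced model for a:\n"); print(x$a_model)
  cat("\nReduced model for b:\n"); print(x$b_model)
  cat(sprintf("\nFixed b (design center): %.4g 1/mM\n", x$b_fixed))
  if (!is.null(x$predictions)) {
    cat("\nPredictions:\n")
    print(format(x$predictions, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Write a deterministic plain-text study report
#'
#' Coefficient tables, ANOVA blocks, the fixed attenuation constant and
#' any predictions, rendered with fixed formatting (3-4 significant
#' figures for constants, scientific notation for p-values) so rerunning
#' on unchanged inputs reproduces the file byte for byte. A reproducibility
#' footer records the package version and the significance/convention
#' settings used.
#'
#' @param bundle a [run_study()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "study_bundle"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Two-level hydrolysis study report: %s", bundle$label)
  add("runs: %d fitted, %d failed", length(bundle$fits) - length(bundle$failed),
      length(bundle$failed))
  add("")
  add("Per-run kinetic constants")
  add("run  x1      x2      a(mM/min)  b(1/mM)   R2")
  for (i in seq_len(nrow(bundle$constants))) {
    r <- bundle$constants[i, ]
    add("%-4d %-7.3g %-7.3g %-10.3g %-9.3g %.4f",
        r$run, r$x1, r$x2, r$a, r$b, r$r_squared)
  }
  model_block <- function(name, m, an) {
    add("")
    add("Reduced model for %s (alpha = %.3g)", name, bundle$alpha)
    add("term         coefficient  se          t          p")
    for (j in seq_along(m$terms)) {
      add("%-12s %-12.4g %-11.3g %-10.4g %.3e",
          m$terms[j], m$coefficients[j], m$se[j], m$t_values[j],
          m$p_values[j])
    }
    add("R2 = %.4f  adj R2 = %.4f", m$r_squared, m$adj_r_squared)
    add("ANOVA (%s convention)", attr(an, "convention"))
    add("source      df  SS           MS           F          p")
    for (j in 1:3) {
      add("%-11s %-3d %-12.6g %-12s %-10s %s",
          an$source[j], an$df[j], an$ss[j],
          if (is.na(an$ms[j])) "" else sprintf("%.6g", an$ms[j]),
          if (is.na(an$f[j])) "" else sprintf("%.4g", an$f[j]),
          if (is.na(an$p[j])) "" else sprintf("%.3e", an$p[j]))
    }
  }
  model_block("a", bundle$a_model, bundle$anova_a)
  model_block("b", bundle$b_model, bundle$anova_b)
  add("")
  add("Fixed b at design center: %.4g 1/mM", bundle$b_fixed)
  if (!is.null(bundle$predictions)) {
    add("")
    add("Predictions")
    add("x1      x2      a_pred     se        ci_low     ci_high    DH_pred(%%)")
    for (i in seq_len(nrow(bundle$predictions))) {
      p <- bundle$predictions[i, ]
      add("%-7.3g %-7.3g %-10.4g %-9.3g %-10.4g %-10.4g %.3g",
          p$x1, p$x2, p$a_pred, p$se_pred, p$ci_low, p$ci_high, p$dh_pred)
    }
  }
  add("")
  add("settings: alpha=%.3g convention=%s package=hydrokin %s",
      bundle$alpha, bundle$convention,
      as.character(utils::packageVersion("hydrokin")))
  writeLines(ln, path)
  invisible(path)
}
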