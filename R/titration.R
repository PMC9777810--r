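#' Assay configuration for pH-stat titration
#'
#' Bundles the constants shared by the titrant-volume to alpha-amino
#' conversion and the degree-of-hydrolysis calculation: the titrant
#' normality N (eq/L), the average degree of dissociation of the released
#' alpha-amino groups at the working pH, the reaction volume V_T (L), the
#' total alpha-amino content of the substrate h_T (meq per g protein) and
#' the protein mass M_P (g) in the reactor.
#'
#' Defaults describe a 40 g milk reaction (3.1\% w/w protein, so 1.24 g
#' protein in approximately 0.040 L at unit density) titrated with 0.5 N
#' NaOH at pH 6.5, where the average dissociation of alpha-amino groups
#' is 0.2 and total hydrolysis yields 10.7 meq alpha-amino groups per gram
#' of milk protein.
#'
#' @param normality titrant concentration, equivalents per liter.
#' @param dissociation average degree of dissociation of released
#'   alpha-amino groups, in (0, 1].
#' @param reaction_volume_l total reaction volume in liters. Values above
#'   5 are assumed to be milliliters and converted, with a message.
#' @param h_total total alpha-amino content, meq per gram of protein.
#' @param protein_mass_g mass of protein in the reaction mixture, grams.
#' @return An object of class `assay_config`.
#' @examples
#' cfg <- assay_config()
#' volume_to_alpha_nh(1, cfg)
#' @export
assay_config <- function(normality = 0.5,
                         dissociation = 0.2,
                         reaction_volume_l = 0.040,
                         h_total = 10.7,
                         protein_mass_g = 1.24) {
  vals <- c(normality = normality, dissociation = dissociation,
            reaction_volume_l = reaction_volume_l, h_total = h_total,
            protein_mass_g = protein_mass_g)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all assay constants must be finite and strictly positive",
         call. = FALSE)
  }
  if (dissociation > 1) {
    stop("`dissociation` is a fraction and must lie in (0, 1]", call. = FALSE)
  }
  if (reaction_volume_l > 5) {
    message("`reaction_volume_l` = ", reaction_volume_l,
            " looks like milliliters; converting to liters")
    reaction_volume_l <- reaction_volume_l / 1000
  }
  structure(
    list(normality = normality, dissociation = dissociation,
         reaction_volume_l = reaction_volume_l, h_total = h_total,
         protein_mass_g = protein_mass_g),
    class = "assay_config"
  )
}

#' @export
print.assay_config <- function(x, ...) {
  cat("pH-stat assay configuration\n")
  cat(sprintf("  titrant normality : %.4g eq/L\n", x$normality))
  cat(sprintf("  dissociation      : %.4g\n", x$dissociation))
  cat(sprintf("  reaction volume   : %.4g L\n", x$reaction_volume_l))
  cat(sprintf("  h_total           : %.4g meq/g protein\n", x$h_total))
  cat(sprintf("  protein mass      : %.4g g\n", x$protein_mass_g))
  invisible(x)
}

#' Convert cumulative titrant volume to released alpha-amino concentration
#'
#' In a pH-stat experiment every proton released by peptide-bond cleavage
#' that is dissociated at the working pH consumes titrant, so the released
#' alpha-amino concentration is `V * N / (dissociation * V_T)` in mM, with
#' `V` the cumulative NaOH volume in mL.
#'
#' @param volume_ml cumulative titrant volume(s), mL. Vectorized.
#' @param config an [assay_config()].
#' @return released alpha-amino group concentration, mM.
#' @examples
#' volume_to_alpha_nh(1, assay_config())  # 62.5 mM
#' @export
volume_to_alpha_nh <- function(volume_ml, config = assay_config()) {
  stopifnot(inherits(config, "assay_config"))
  if (any(!is.finite(volume_ml))) {
    stop("titrant volumes must be finite", call. = FALSE)
  }
  if (any(volume_ml < 0)) {
    stop("titrant volumes must be non-negative", call. = FALSE)
  }
  volume_ml * config$normality /
    (config$dissociation * config$reaction_volume_l)
}

#' Convert released alpha-amino concentration to degree of hydrolysis
#'
#' The degree of hydrolysis is the fraction of peptide bonds cleaved:
#' released alpha-amino equivalents `P * V_T` over the total available
#' `h_total * protein_mass_g`.
#'
#' @param concentration_mm released alpha-amino concentration, mM.
#' @param config an [assay_config()].
#' @param percent report percent (default) rather than a fraction.
#' @return degree of hydrolysis, percent or fraction.
#' @examples
#' alpha_nh_to_dh(62.1, assay_config())  # ~18.7 %
#' @export
alpha_nh_to_dh <- function(concentration_mm, config = assay_config(),
                           percent = TRUE) {
  stopifnot(inherits(config, "assay_config"))
  if (any(concentration_mm < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  dh <- concentration_mm * config$reaction_volume_l /
    (config$h_total * config$protein_mass_g)
  if (percent) 100 * dh else dh
}

#' Hydrolysis curve: released product concentration over time
#'
#' @param times reaction times, minutes, non-decreasing.
#' @param product released alpha-amino concentration, mM, same length.
#' @return An object of class `hydrolysis_curve` (also a data.frame with
#'   columns `time` and `product`).
#' @export
hydrolysis_curve <- function(times, product) {
  if (length(times) != length(product)) {
    stop("`times` and `product` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(product))) {
    stop("times and product values must be finite", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(product < -1e-9)) {
    stop("product concentrations must be non-negative", call. = FALSE)
  }
  ord <- order(times)
  times <- times[ord]
  product <- pmax(product[ord], 0)
  if (anyDuplicated(times)) {
    stop("times must be unique within a curve", call. = FALSE)
  }
  structure(
    data.frame(time = times, product = product),
    class = c("hydrolysis_curve", "data.frame")
  )
}

#' @export
print.hydrolysis_curve <- function(x, ...) {
  cat(sprintf(
    "Hydrolysis curve: %d points, t = [%.4g, %.4g] min, P(max) = %.4g mM\n",
    nrow(x), min(x$time), max(x$time), max(x$product)))
  invisible(x)
}

#' Build a hydrolysis curve from a pH-stat titration trace
#'
#' Applies [volume_to_alpha_nh()] pointwise to a cumulative titrant volume
#' record. The cumulative volume must be non-decreasing; instrument traces
#' that transiently decrease can be repaired with a running maximum by
#' setting `repair = TRUE` (off by default: a decreasing trace is an error).
#'
#' @param trace data.frame with columns `time` and `volume` (cumulative mL).
#' @param config an [assay_config()].
#' @param downsample optional target number of points; points are kept
#'   uniformly in index and the first and last points are always retained.
#' @param time_unit `"min"` (default) or `"s"`; seconds are converted.
#' @param repair replace a decreasing cumulative volume by its running
#'   maximum (with a warning) instead of failing.
#' @return A [hydrolysis_curve()].
#' @export
trace_to_curve <- function(trace, config = assay_config(), downsample = NULL,
                           time_unit = c("min", "s"), repair = FALSE) {
  time_unit <- match.arg(time_unit)
  if (!is.data.frame(trace) || !all(c("time", "volume") %in% names(trace))) {
    stop("`trace` must be a data.frame with columns `time` and `volume`",
         call. = FALSE)
  }
  if (nrow(trace) == 0) stop("empty titration trace", call. = FALSE)
  tt <- as.numeric(trace$time)
  vv <- as.numeric(trace$volume)
  if (any(!is.finite(tt)) || any(!is.finite(vv))) {
    stop("titration trace contains non-finite values", call. = FALSE)
  }
  ord <- order(tt)
  tt <- tt[ord]; vv <- vv[ord]
  if (anyDuplicated(tt)) {
    stop("titration times must be unique", call. = FALSE)
  }
  if (time_unit == "s") tt <- tt / 60
  if (is.unsorted(vv)) {
    if (repair) {
      warning("cumulative titrant volume decreases; applying running maximum")
      vv <- cummax(vv)
    } else {
      stop("cumulative titrant volume decreases within the trace ",
           "(set `repair = TRUE` to apply a running maximum)", call. = FALSE)
    }
  }
  if (!is.null(downsample)) {
    downsample <- as.integer(downsample)
    if (downsample < 2) stop("`downsample` must be at least 2", call. = FALSE)
    if (downsample < length(tt)) {
      idx <- unique(round(seq(1L, length(tt), length.out = downsample)))
      tt <- tt[idx]; vv <- vv[idx]
    }
  }
  hydrolysis_curve(tt, volume_to_alpha_nh(vv, config))
}
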