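# Published milk-hydrolysis study data: the coded central composite design
# and the per-run kinetic constants fitted to the pH-stat curves for the
# three commercial proteases. These constants are the inputs to the
# second-level response-surface regression.

#' Variable codings of the milk hydrolysis study
#'
#' Temperature T: 48-62 deg C, center 55, step 5 per coded unit.
#' Protease dose E: 19-231 mAU, center 125, step 75 per coded unit.
#' Axial distance sqrt(2) (printed design levels +/-1.4 are the rounded
#' display of +/-sqrt(2): 55 - 5*sqrt(2) = 47.93 ~ 48 deg C).
#'
#' @return list of two [variable_coding()]s, `T` and `E`.
#' @export
milk_study_codings <- function() {
  list(T = variable_coding("T", center = 55, step = 5, axial = sqrt(2)),
       E = variable_coding("E", center = 125, step = 75, axial = sqrt(2)))
}

#' Coded design of the milk hydrolysis study
#'
#' The ten-run central composite circumscribed design in the published
#' run order: axial/factorial/center rows interleaved as executed, with
#' center replicates in runs 5 and 10. Row order matches
#' [milk_kinetic_constants()].
#'
#' @return A [build_ccc()]-compatible `ccc_design` whose `points` rows are
#'   in study run order.
#' @export
milk_study_design <- function() {
  dsn <- build_ccc(unname(milk_study_codings()), n_center = 2)
  s2 <- sqrt(2)
  pts <- cbind(
    x1 = c(-s2, -1, -1, 0, 0, 0, 1, 1, s2, 0),
    x2 = c(0, 1, -1, s2, 0, -s2, 1, -1, 0, 0))
  dsn$points <- pts
  dsn
}

#' Kinetic constants fitted to the milk hydrolysis study curves
#'
#' Per-run logarithmic-model constants (3 significant figures) for the
#' ten design runs, by protease. `a` is the initial hydrolysis rate
#' (mM/min), `b` the attenuation constant (1/mM), `r_squared` the
#' per-curve fit quality.
#'
#' @param protease `"Alcalase"`, `"Neutrase"` or `"Protamex"`; `"all"`
#'   (default) returns the three stacked with a `protease` column.
#' @return data.frame with columns `run`, `x1`, `x2`, `a`, `b`,
#'   `r_squared` (and `protease` when `protease = "all"`).
#' @examples
#' reduce_model(milk_study_design(), milk_kinetic_constants("Alcalase")$a)
#' @export
milk_kinetic_constants <- function(protease = c("all", "Alcalase",
                                                "Neutrase", "Protamex")) {
  protease <- match.arg(protease)
  pts <- milk_study_design()$points
  base <- data.frame(run = 1:10, x1 = pts[, "x1"], x2 = pts[, "x2"])
  tabs <- list(
    Alcalase = data.frame(
      a = c(4.06, 7.56, 2.89, 15.2, 9.46, 2.15, 21.7, 5.76, 17.8, 10.4),
      b = c(0.0494, 0.0432, 0.0498, 0.0356, 0.0359, 0.0508, 0.0361,
            0.0353, 0.0343, 0.0401),
      r_squared = c(0.9940, 0.9955, 0.9955, 0.9980, 0.9928, 0.9987,
                    0.9990, 0.9974, 0.9981, 0.9962)),
    Neutrase = data.frame(
      a = c(25.6, 30.2, 8.76, 42.7, 26.3, 4.96, 86.5, 22.0, 105.8, 37.7),
      b = c(0.135, 0.104, 0.105, 0.080, 0.082, 0.082, 0.078, 0.085,
            0.090, 0.084),
      r_squared = c(0.9967, 0.9923, 0.9996, 0.9985, 0.9993, 0.9993,
                    0.9933, 0.9934, 0.9866, 0.9989)),
    Protamex = data.frame(
      a = c(9.15, 16.5, 4.36, 26.6, 16.1, 2.93, 40.7, 9.44, 30.2, 16.5),
      b = c(0.0631, 0.0509, 0.0542, 0.0409, 0.0407, 0.0498, 0.0386,
            0.0392, 0.0411, 0.0399),
      r_squared = c(0.9966, 0.9983, 0.9980, 0.9991, 0.9990, 0.9981,
                    0.9979, 0.9993, 0.9967, 0.9990)))
  if (protease != "all") {
    return(cbind(base, tabs[[protease]]))
  }
  do.call(rbind, lapply(names(tabs), function(nm) {
    cbind(base, protease = nm, tabs[[nm]])
  }))
}

#' Validation conditions of the milk hydrolysis study
#'
#' The four additional coded conditions used to test predictability,
#' with the experimentally fitted initial rates for Alcalase and
#' Protamex and the experimental degree of hydrolysis after 60 min.
#'
#' @return data.frame with columns `run`, `x1`, `x2`, `a_exp_alcalase`,
#'   `a_exp_protamex`, `dh_exp_alcalase`, `dh_exp_protamex`.
#' @export
milk_validation_conditions <- function() {
  data.frame(
    run = 11:14,
    x1 = c(-0.5, 0.5, 0, 0),
    x2 = c(0, 0, -1, 1),
    a_exp_alcalase = c(9.10, 10.2, 3.92, 13.8),
    a_exp_protamex = c(17.0, 16.9, 7.44, 25.9),
    dh_exp_alcalase = c(25.7, 24.8, 19.6, 27.2),
    dh_exp_protamex = c(29.6, 27.5, 23.4, 30.1))
}
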