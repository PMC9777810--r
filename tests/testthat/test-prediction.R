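test_that("predicted initial rates reproduce the published validation table", {
  dsn <- milk_study_design()
  m_alc <- fit_polynomial(dsn, tab_alcalase$a, TERMS_INT)
  m_pro <- fit_polynomial(dsn, tab_protamex$a, TERMS_INT)

  # Alcalase predictions and standard errors at the four validation
  # points; the published +/- column estimates sigma^2 under the study's
  # own df convention
  pr <- predict_a(m_alc, c(-0.5, 0), convention = "paper")
  expect_equal(pr$a_pred, 7.41, tolerance = 0.01)
  expect_equal(pr$se_pred, 0.44, tolerance = 0.02)
  expect_equal(predict_a(m_alc, c(0.5, 0))$a_pred, 12.0, tolerance = 0.01)
  expect_equal(predict_a(m_alc, c(0, -1))$a_pred, 4.81, tolerance = 0.01)
  expect_equal(predict_a(m_alc, c(0, 1))$a_pred, 14.6, tolerance = 0.01)
  expect_equal(predict_a(m_alc, c(0, 1), convention = "paper")$se_pred,
               0.58, tolerance = 0.02)

  expect_equal(predict_a(m_pro, c(0, -1))$a_pred, 7.65, tolerance = 0.01)
  expect_equal(predict_a(m_pro, c(0, 1))$a_pred, 26.8, tolerance = 0.01)
  expect_equal(predict_a(m_pro, c(-0.5, 0))$a_pred, 13.6, tolerance = 0.01)
  expect_equal(predict_a(m_pro, c(0.5, 0))$a_pred, 21.0, tolerance = 0.01)
})

test_that("prediction machinery satisfies its structural identities", {
  dsn <- milk_study_design()
  m <- fit_polynomial(dsn, tab_alcalase$a, TERMS_INT)
  # at the center, a model without pure quadratics predicts the intercept
  expect_equal(predict_a(m, c(0, 0))$a_pred,
               unname(m$coefficients["(Intercept)"]), tolerance = 1e-12)
  # hat-matrix identity: prediction at each design point = fitted value
  full <- fit_polynomial(dsn, tab_alcalase$a)
  for (i in 1:10) {
    expect_equal(predict_a(full, dsn$points[i, ])$a_pred, full$fitted[i],
                 tolerance = 1e-10)
  }
  # band nesting: higher confidence never narrows the interval
  p90 <- predict_a(m, c(0.7, -0.3), confidence = 0.90)
  p95 <- predict_a(m, c(0.7, -0.3), confidence = 0.95)
  p99 <- predict_a(m, c(0.7, -0.3), confidence = 0.99)
  expect_lte(p95$ci_low, p90$ci_low)
  expect_gte(p95$ci_high, p90$ci_high)
  expect_lte(p99$ci_low, p95$ci_low)
  expect_gte(p99$ci_high, p95$ci_high)
  # leverage is minimal at the design center over the coded square
  g <- expand.grid(x1 = seq(-1, 1, 0.25), x2 = seq(-1, 1, 0.25))
  se_grid <- vapply(seq_len(nrow(g)),
                    function(i) predict_a(m, as.numeric(g[i, ]))$se_pred, 0)
  expect_equal(min(se_grid), predict_a(m, c(0, 0))$se_pred)
  # extrapolation warns but still returns a result
  expect_warning(pr <- predict_a(m, c(2, 0)), "extrapolat")
  expect_true(is.finite(pr$a_pred))
})

test_that("predicted 60-min DH reproduces the published validation values", {
  dsn <- milk_study_design()
  cfg <- assay_config()
  m_alc <- fit_polynomial(dsn, tab_alcalase$a, TERMS_INT)
  m_pro <- fit_polynomial(dsn, tab_protamex$a, TERMS_INT)
  b_alc <- fixed_b(reduce_model(dsn, tab_alcalase$b))
  b_pro <- fixed_b(reduce_model(dsn, tab_protamex$b))

  dh60 <- function(model, x0, b) {
    pc <- predict_curve(predict_a(model, x0), b, times = c(0, 60), cfg)
    pc$dh_mid[2]
  }
  printed_alc <- c(21.8, 25.2, 18.8, 26.6)
  printed_pro <- c(25.5, 28.5, 21.6, 30.3)
  pts <- list(c(-0.5, 0), c(0.5, 0), c(0, -1), c(0, 1))
  for (i in seq_along(pts)) {
    expect_equal(dh60(m_alc, pts[[i]], b_alc), printed_alc[i],
                 tolerance = 0.015, label = sprintf("Alcalase DH point %d", i))
    expect_equal(dh60(m_pro, pts[[i]], b_pro), printed_pro[i],
                 tolerance = 0.015, label = sprintf("Protamex DH point %d", i))
  }
})

test_that("predicted curves carry ordered, monotone confidence bands", {
  dsn <- milk_study_design()
  m <- fit_polynomial(dsn, tab_alcalase$a, TERMS_INT)
  pc <- predict_curve(predict_a(m, c(0, -1)), 0.0410, times = seq(0, 60, 2))
  expect_true(all(pc$p_low <= pc$p_mid + 1e-12))
  expect_true(all(pc$p_mid <= pc$p_high + 1e-12))
  expect_equal(pc$p_mid[1], 0)
  expect_equal(pc$dh_low[1], 0)
  expect_true(all(diff(pc$p_mid) > 0))
  # degenerate zero-width interval collapses the band onto the midline
  pr <- predict_a(m, c(0, 0))
  pr$ci_low <- pr$ci_high <- pr$a_pred
  pc0 <- predict_curve(pr, 0.0410, times = c(0, 30, 60))
  expect_equal(pc0$p_low, pc0$p_mid)
  expect_equal(pc0$p_high, pc0$p_mid)
  # negative lower limit clamps to zero with a warning
  pr$ci_low <- -1
  expect_warning(pc_neg <- predict_curve(pr, 0.0410, times = c(0, 60)),
                 "clamping")
  expect_equal(pc_neg$p_low, c(0, 0))
})

test_that("percent error and validation correlation behave as defined", {
  expect_equal(percent_error(14.6, 13.8), 5.7, tolerance = 0.02)
  expect_equal(percent_error(4.81, 3.92), 22.7, tolerance = 0.005)
  expect_equal(percent_error(5, 5), 0)
  expect_error(percent_error(1, 0), "zero")

  expect_equal(validation_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  # sign-blind: anti-correlated series also score 1
  expect_equal(validation_correlation(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_error(validation_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(validation_correlation(1, c(1, 2)), "equal-length")

  # informational: predicted-vs-experimental correlation across the two
  # validated proteases is high
  val <- milk_validation_conditions()
  dsn <- milk_study_design()
  m_alc <- fit_polynomial(dsn, tab_alcalase$a, TERMS_INT)
  m_pro <- fit_polynomial(dsn, tab_protamex$a, TERMS_INT)
  pred <- c(vapply(1:4, function(i) predict_a(m_alc, c(val$x1[i], val$x2[i]))$a_pred, 0),
            vapply(1:4, function(i) predict_a(m_pro, c(val$x1[i], val$x2[i]))$a_pred, 0))
  expt <- c(val$a_exp_alcalase, val$a_exp_protamex)
  expect_gt(validation_correlation(pred, expt), 0.9)
})
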