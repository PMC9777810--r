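test_that("the circumscribed design has the right geometry", {
  dsn <- build_ccc(n_center = 2)
  pts <- dsn$points
  expect_equal(nrow(pts), 10)
  expect_equal(nrow(build_ccc(n_center = 1)$points), 9)
  # set equality with the published run order
  pub <- milk_study_design()$points
  key <- function(m) sort(paste(round(m[, 1], 6), round(m[, 2], 6)))
  expect_equal(key(pts), key(pub))
  # column sums of x1, x2 and the interaction vanish
  expect_equal(colSums(pts), c(x1 = 0, x2 = 0))
  expect_equal(sum(pts[, 1] * pts[, 2]), 0)
  # factorial corners and axial points present
  expect_equal(sum(abs(pts[, 1]) == 1 & abs(pts[, 2]) == 1), 4)
  expect_equal(sum(abs(pts[, 1]) > 1.41 | abs(pts[, 2]) > 1.41), 4)
})

test_that("coded units decode to the published natural levels", {
  cod <- milk_study_codings()
  expect_equal(decode(cod$T, -sqrt(2)), 47.93, tolerance = 1e-3)
  expect_equal(round(decode(cod$T, c(-sqrt(2), -1, 0, 1, sqrt(2)))),
               c(48, 50, 55, 60, 62))
  expect_equal(round(decode(cod$E, c(-sqrt(2), -1, 0, 1, sqrt(2)))),
               c(19, 50, 125, 200, 231))
  expect_equal(decode(cod$E, 0), 125)
  # encode inverts decode to machine precision
  x <- runif(10, -2, 2)
  expect_equal(encode(cod$T, decode(cod$T, x)), x)
})

test_that("matrix OLS matches closed-form coefficients on the orthogonal design", {
  dsn <- milk_study_design()
  pts <- dsn$points
  set.seed(2)
  for (rep in 1:5) {
    y <- rnorm(10, 10, 4)
    m <- fit_polynomial(dsn, y, TERMS_INT)
    # orthogonality: beta_j = sum(x_j * y) / sum(x_j^2), beta_0 = mean(y)
    expect_equal(unname(m$coefficients["(Intercept)"]), mean(y),
                 tolerance = 1e-10)
    expect_equal(unname(m$coefficients["x1"]),
                 sum(pts[, 1] * y) / sum(pts[, 1]^2), tolerance = 1e-10)
    expect_equal(unname(m$coefficients["x2"]),
                 sum(pts[, 2] * y) / sum(pts[, 2]^2), tolerance = 1e-10)
    expect_equal(unname(m$coefficients["x1:x2"]),
                 sum(pts[, 1] * pts[, 2] * y) / sum((pts[, 1] * pts[, 2])^2),
                 tolerance = 1e-10)
  }
})

test_that("refitting the published responses reproduces the printed models", {
  dsn <- milk_study_design()
  check <- function(y, terms, printed, tol = 0.02) {
    m <- fit_polynomial(dsn, y, terms)
    for (nm in names(printed)) {
      expect_equal(unname(m$coefficients[nm]), printed[[nm]],
                   tolerance = tol, label = paste("coefficient", nm))
    }
    m
  }
  # initial-rate models
  check(tab_alcalase$a, TERMS_INT,
        c("(Intercept)" = 9.69, "x1" = 4.56, "x2" = 4.88, "x1:x2" = 2.82))
  check(tab_protamex$a, TERMS_INT,
        c("(Intercept)" = 17.25, "x1" = 7.40, "x2" = 9.60, "x1:x2" = 4.79))
  check(tab_neutrase$a, TERMS_SQ1,
        c("(Intercept)" = 25.07, "x1" = 22.86, "x2" = 17.41, "x1^2" = 17.49))
  # attenuation-constant models
  check(tab_alcalase$b, c("(Intercept)", "x1", "x2"),
        c("(Intercept)" = 0.0410, "x1" = -0.00537, "x2" = -0.00344))
  check(tab_neutrase$b, c("(Intercept)", "x1", "x1^2"),
        c("(Intercept)" = 0.0809, "x1" = -0.0135, "x1^2" = 0.0147))
  check(tab_protamex$b, c("(Intercept)", "x1", "x1^2"),
        c("(Intercept)" = 0.0423, "x1" = -0.00731, "x1^2" = 0.00436))
  # fit-quality statistics of the printed Alcalase a-model
  m <- fit_polynomial(dsn, tab_alcalase$a, TERMS_INT)
  expect_equal(m$r_squared, 0.9814, tolerance = 1e-3)
  expect_equal(m$adj_r_squared, 0.9721, tolerance = 1e-3)
})

test_that("backward elimination recovers the published reduced forms", {
  dsn <- milk_study_design()
  expect_equal(reduce_model(dsn, tab_alcalase$a)$terms, TERMS_INT)
  expect_equal(reduce_model(dsn, tab_protamex$a)$terms, TERMS_INT)
  expect_equal(reduce_model(dsn, tab_alcalase$b)$terms,
               c("(Intercept)", "x1", "x2"))
  expect_equal(reduce_model(dsn, tab_neutrase$b)$terms,
               c("(Intercept)", "x1", "x1^2"))
  expect_equal(reduce_model(dsn, tab_protamex$b)$terms,
               c("(Intercept)", "x1", "x1^2"))
  # the Neutrase initial-rate curvature term sits at the significance
  # boundary on 3-s.f. inputs: worst-term-at-a-time elimination retains it
  expect_equal(reduce_model(dsn, tab_neutrase$a, method = "iterative")$terms,
               TERMS_SQ1)
})

test_that("elimination is idempotent and collapses pure noise", {
  dsn <- milk_study_design()
  red <- reduce_model(dsn, tab_alcalase$a)
  again <- reduce_model(dsn, tab_alcalase$a, terms = red$terms)
  expect_equal(again$terms, red$terms)
  expect_equal(again$coefficients, red$coefficients)
  # under the null, the intercept-only model should be selected almost always
  set.seed(19)
  n_intercept_only <- 0
  for (i in 1:100) {
    m <- reduce_model(dsn, rnorm(10))
    if (identical(m$terms, "(Intercept)")) n_intercept_only <- n_intercept_only + 1
  }
  expect_gte(n_intercept_only, 75)  # 5 null terms at alpha = 0.05
})

test_that("ANOVA decomposes variance under both df conventions", {
  dsn <- milk_study_design()
  m <- fit_polynomial(dsn, tab_alcalase$a, TERMS_INT)
  an_paper <- anova_table(m, "paper")
  expect_equal(an_paper$df, c(4, 5, 9))
  expect_equal(an_paper$ss[3], an_paper$ss[1] + an_paper$ss[2],
               tolerance = 1e-8)
  # published block: SS_reg 388.86, MS_err 1.472, F 66.04 (computed there
  # from unrounded raw fits; 3-s.f. inputs shift the error SS by a few %)
  expect_equal(an_paper$ss[1], 388.86, tolerance = 2e-3)
  expect_equal(an_paper$ms[2], 1.472, tolerance = 0.03)
  expect_equal(an_paper$f[1], 66.04, tolerance = 0.03)
  an_std <- anova_table(m, "standard")
  expect_equal(an_std$df, c(3, 6, 9))
  expect_equal(an_std$ss, an_paper$ss)
  expect_error(anova_table(m, "bogus"))
})

test_that("the fixed attenuation constant is the reduced model's center value", {
  dsn <- milk_study_design()
  expect_equal(fixed_b(reduce_model(dsn, tab_alcalase$b)), 0.0410,
               tolerance = 0.01)
  expect_equal(fixed_b(reduce_model(dsn, tab_protamex$b)), 0.0423,
               tolerance = 0.01)
  # for a model without pure quadratics this equals the plain mean
  expect_equal(fixed_b(reduce_model(dsn, tab_alcalase$b)),
               fixed_b(tab_alcalase$b))
  expect_equal(fixed_b(rep(0.05, 10)), 0.05)
})

test_that("singular and malformed regressions fail loudly", {
  dsn <- milk_study_design()
  # duplicating x1 as x1^2 cannot happen with the fixed term set, but a
  # zero-variance pseudo-design can: all rows at the center
  degen <- matrix(0, nrow = 8, ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  expect_error(fit_polynomial(degen, rnorm(8), c("(Intercept)", "x1")),
               "singular|collinear")
  expect_error(fit_polynomial(dsn, rnorm(9)), "does not match")
  expect_error(fit_polynomial(dsn, rnorm(10), c("x1", "x2")), "Intercept")
  expect_error(fit_polynomial(dsn, rnorm(10),
                              c("(Intercept)", "x1", "x9")), "unknown")
})

test_that("simulated second-level data recovers its generating terms", {
  # responses drawn from a known reduced model with noise scaled for
  # R^2 ~ 0.97 should select the true support most of the time
  dsn <- milk_study_design()
  X <- cbind(1, dsn$points[, 1], dsn$points[, 2],
             dsn$points[, 1] * dsn$points[, 2])
  beta <- c(9.69, 4.56, 4.88, 2.82)
  mu <- drop(X %*% beta)
  # sd chosen so that expected R^2 = 1 - n*sd^2/SST ~ 0.97
  sd_noise <- sqrt(0.03 * sum((mu - mean(mu))^2) / 10)
  set.seed(23)
  hits <- 0
  for (i in 1:100) {
    m <- reduce_model(dsn, mu + rnorm(10, sd = sd_noise))
    if (identical(m$terms, TERMS_INT)) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
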