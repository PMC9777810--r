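# Shared fixtures and independent oracles.

# Grid-search + local-polish estimator of the logarithmic-model constants,
# deliberately independent of the package's Levenberg-Marquardt route:
# coarse 200x200 log-spaced grid on (a, b) followed by Nelder-Mead polish
# of the plain SSE objective.
grid_fit_oracle <- function(times, product, n_grid = 200) {
  p_max <- max(product)
  a_grid <- exp(seq(log(p_max / max(times) / 50), log(50 * p_max),
                    length.out = n_grid))
  b_grid <- exp(seq(log(1e-4), log(10 / p_max), length.out = n_grid))
  sse <- function(a, b) sum((product - log1p(a * b * times) / b)^2)
  best <- c(NA, NA); best_sse <- Inf
  for (a in a_grid) {
    # vectorize over b for speed
    s <- vapply(b_grid, function(b) sse(a, b), 0)
    i <- which.min(s)
    if (s[i] < best_sse) { best_sse <- s[i]; best <- c(a, b_grid[i]) }
  }
  pol <- optim(log(best), function(lp) sse(exp(lp[1]), exp(lp[2])),
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  exp(pol$par)
}

# Closed form of dP/dt = a*exp(-b*P)*exp(-kd*t), P(0) = 0 — obtained by the
# time change tau = (1 - exp(-kd*t))/kd, under which the rate law loses its
# explicit time dependence. Independent check on the RK4 simulator.
inactivated_log_model <- function(a, b, kd, t) {
  tau <- if (kd == 0) t else (1 - exp(-kd * t)) / kd
  log1p(a * b * tau) / b
}

# Published per-protease kinetic constants, as plain data.frames.
tab_alcalase <- milk_kinetic_constants("Alcalase")
tab_neutrase <- milk_kinetic_constants("Neutrase")
tab_protamex <- milk_kinetic_constants("Protamex")

# Term-set shorthands.
TERMS_INT  <- c("(Intercept)", "x1", "x2", "x1:x2")
TERMS_SQ1  <- c("(Intercept)", "x1", "x2", "x1^2")
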