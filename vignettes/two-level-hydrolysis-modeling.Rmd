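---
title: "Two-level modeling of enzymatic milk protein hydrolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level modeling of enzymatic milk protein hydrolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrokin)
```

## The measurement and its stoichiometry

A pH-stat hydrolysis experiment holds the pH of a milk-protein solution
constant while a protease cleaves peptide bonds. Each cleavage exposes an
α-amino group; the fraction α of those groups that deprotonates at the
working pH releases a proton, which the autotitrator neutralizes with
NaOH. The cumulative titrant volume V (mL) is therefore a stoichiometric
proxy for reaction progress:

$$P = \frac{V N}{\alpha V_T}, \qquad
  \mathrm{DH} = \frac{P\,V_T}{h_T M_P},$$

with P the released α-amino concentration (mM), N the titrant normality
(eq/L), $V_T$ the reaction volume (L), $h_T$ the total α-amino content
(meq per g protein) and $M_P$ the protein mass (g). DH is the degree of
hydrolysis — the fraction of peptide bonds cleaved.

`assay_config()` carries these five constants. The defaults describe a
40 g milk reaction at 3.1% (w/w) protein titrated with 0.5 N NaOH at
pH 6.5: α = 0.2, $h_T$ = 10.7 meq/g, $M_P$ = 1.24 g. The reaction volume
is not itself a measured quantity here; 40 g of milk at approximately
unit density gives $V_T$ = 0.040 L, and with that value the DH numbers
produced by the conversion chain agree with the validation DH table to
well under 1%. $V_T$ is user-overridable for other reactor loadings.
Two deliberate simplifications: the titrant added is treated as not
diluting $V_T$ (the stoichiometric relation above assumes a constant
reaction volume), and α is a single averaged constant — no
temperature or pH correction of the dissociation equilibrium is applied,
since the assay operates at one pH and the temperature range is narrow.
Time is minutes throughout; traces sampled in seconds are accepted with
`time_unit = "s"`.

## First level: the logarithmic curve model

Each curve is summarized by the two-parameter rate law
$dP/dt = a e^{-bP}$, whose closed form is

$$P(t) = \frac{1}{b}\ln(a b t + 1).$$

The constant *a* (mM/min) is exactly the initial slope $dP/dt|_{t=0}$,
and $1/b$ (mM) is the product scale over which the rate attenuates —
jointly they capture the fast-start/slow-finish shape of protease
kinetics without committing to a mechanism (substrate depletion, product
inhibition and enzyme inactivation all produce curves of roughly this
shape). The model is empirical; the package does not attempt
Michaelis–Menten style mechanistic fitting.

`fit_log_model()` estimates (a, b) by bounded Levenberg–Marquardt least
squares:

* **Initialization.** $a_0$ = the slope of a straight-line fit through
  the first 10% of points (at least two): *a* is an initial slope, so the
  early data estimate it directly. $b_0 = 1/\max(P)$: the curve's
  saturation scale. On failure, restarts at $b_0 \times \{0.1, 1, 10\}$.
* **Bounds and tolerances.** Both constants bounded below at $10^{-12}$;
  convergence tolerances $10^{-12}$ on cost and step, 200 iterations.
  If $\hat b$ lands on its bound the curve is effectively linear and the
  linear-limit fit $P = at$ is reported with a warning.
* **Inference.** $\hat\sigma^2 = \mathrm{SSE}/(n-2)$ (two fitted
  parameters — the usual nonlinear least-squares convention),
  $se_j = \sqrt{\hat\sigma^2 C_{jj}}$ with $C = (J^\top J)^{-1}$ and J
  the analytic Jacobian at the optimum, and $R^2$ computed about the mean
  of the observations.

The tests hold this fitter to an independent oracle — a 200×200
log-spaced grid search with Nelder–Mead polish on the raw SSE — within
0.5% on seeded noisy curves, and to sub-0.1% self-consistency when
refitting noiseless curves generated from each published constant pair.

## Second level: response-surface regression

Operating conditions enter in coded units,
$x = (\text{natural} - \text{center})/\text{step}$: temperature centered
at 55 °C with a 5 °C step, protease dose centered at 125 mAU with a
75 mAU step. The design is a two-factor central composite circumscribed
design — factorial corners (±1, ±1), axial points at ±√2, and replicated
center points. The axial distance is taken as exactly √2 rather than the
display-rounded 1.4: the natural axial levels (48/62 °C, 19/231 mAU)
back-transform to ±√2, not ±1.40.

`fit_polynomial()` is ordinary least squares of a response (a or b) on a
subset of $\{1, x_1, x_2, x_1^2, x_2^2, x_1x_2\}$, with per-term t-tests
at $n - p$ degrees of freedom. On this design the linear and interaction
columns are mutually orthogonal, so their coefficients have closed forms
($\beta_j = \sum x_j y / \sum x_j^2$) that the tests check against the
matrix algebra at $10^{-10}$.

**Model reduction.** `reduce_model()` removes non-significant terms at
α = 0.05. Two strategies are provided because the literature uses both
and they can disagree on borderline terms. The default, `"single"`, fits
the full quadratic once and drops every term with p > α together — the
classic reduce-the-polynomial step of applied response-surface work.
`"iterative"` drops the single worst term and refits until all survivors
are significant; it is the more conservative choice and can retain
curvature terms whose p-value drifts just under α as degrees of freedom
accumulate. On the built-in study constants the default reproduces the
reduced forms of five of the six published models; the Neutrase
initial-rate model, whose $x_1^2$ term sits almost exactly at the 5%
boundary when refit from 3-significant-figure inputs, is recovered by
the iterative strategy. α = 0.05 itself is the smallest conventional
level consistent with every retained published coefficient.

**ANOVA conventions.** `anova_table()` offers the textbook convention
(regression df = p − 1, error df = n − p) and a `"paper"` convention
(regression df = p, error df = n − p − 1) that counts the intercept among
the regression degrees of freedom — applied response-surface reports
sometimes tabulate it this way, and the study this package reproduces is
internally consistent only under it. The same flag in `predict_a()`
applies the chosen error df both to $\hat\sigma^2$ and to the t quantile.
The default everywhere is `"standard"`.

**Fixed b.** When b correlates only weakly with the conditions, curve
prediction holds it at the design-center value of its reduced model —
the intercept, which on this orthogonal design equals the plain mean of
the b values whenever no pure-quadratic term is retained.

## Prediction

`predict_a()` evaluates a fitted model at a coded condition $x_0$ with
the confidence interval
$\hat y(x_0) \pm t_{\alpha/2,\mathrm{df}}\sqrt{\hat\sigma^2\, x_0^\top (X^\top X)^{-1} x_0}$.
This is the interval of the regression mean (no +1 new-observation
term), which is what a dashed band around a predicted mean curve
represents. Conditions outside the axial radius warn as extrapolations
but are computed.

`predict_curve()` propagates the interval through the first-level model
with b fixed. Because $P(t)$ is strictly increasing in *a*, evaluating
the curve at the interval endpoints yields the exact band — no
delta-method linearization is needed, and the band inherits the interval's
coverage statement. Only the uncertainty in *a* is propagated; treating b
as a known constant understates the band width to the extent that the
center b estimate is itself uncertain. A negative lower limit for *a*
(possible at low-leverage conditions with few df) is clamped to zero with
a warning, since a negative initial rate is physically meaningless.

## What the simulator emulates — and what it does not

`simulation_scenario()` + `simulate_design_study()` generate complete
synthetic studies so the whole pipeline can be validated without
laboratory data:

* **Kinetics.** $dP/dt = a e^{-bP} e^{-k_d t}$, integrated by
  fixed-step fourth-order Runge–Kutta with step ≤ 0.01 min. The rate law
  is smooth and cheap, so RK4 at this step carries error orders of
  magnitude below any tolerance used in testing; with $k_d = 0$ the
  trajectory matches the closed form to $10^{-6}$ relative. The
  inactivation term emulates a thermolabile protease (a 10-min half-life
  reproduces the plateauing curves of a metalloprotease near 60 °C);
  the tests deliberately fit such curves with the stable-enzyme model,
  as one would in practice, and verify the fit degrades rather than
  fails.
* **Instrument.** Noise is added to the *titrant volume* — the quantity
  the instrument actually measures — then a running maximum restores the
  monotonicity a cumulative burette reading must have, then the volume is
  quantized to the dispensing resolution. One integer seed drives each
  run's stream, making every fixture bit-reproducible.
* **Study conditions.** The default geometry mirrors the real study: a
  10-run design, 60-min runs. The end-to-end recovery tests sample every
  15 s (241 points per curve) rather than at the instrument's 1 Hz: the
  per-curve information at 241 points is already far beyond what the
  recovery tolerances require, and the titration/downsampling tests
  separately confirm that fitted constants are insensitive to sampling
  density. The titrant noise in those tests, 0.02 mL, is calibrated so
  the simulated per-curve fit quality lands in the published range (all
  $R^2 > 0.99$, median ≈ 0.998).

The simulator does **not** model substrate depletion by mass balance,
product inhibition, temperature-dependent inactivation laws (k_d is
specified per scenario, not derived from an Arrhenius relation), pH
drift between titrant additions, or correlated instrument noise. Passing
recovery tests therefore demonstrate that the estimation chain is
correct and well-conditioned under the model's own assumptions — not
that real curves obey the logarithmic law, which must be judged from the
per-curve $R^2$ and residuals of real data.

A caution from the simulator's own behavior: the running-maximum step is
faithful to a cumulative instrument but acts as a one-sided filter. At
noise levels far above realistic (several times the per-sample titrant
increment) it inflates the apparent curve and biases fitted initial
rates upward. This is a property of any monotonized cumulative record,
worth remembering when a real titrator's noise is large relative to its
dosing rate.

## Numerical and degenerate-input choices

* Curves need ≥ 4 points and at least one positive product value; all-zero
  curves are rejected as degenerate rather than "fit" with b at a bound.
* Curve times must be unique; unsorted input is sorted, and a decreasing
  cumulative volume is an error unless `repair = TRUE` explicitly opts
  into running-maximum correction.
* Downsampling is uniform in index and always keeps both endpoints, so a
  downsampled trace spans the same time window.
* `fit_polynomial()` refuses singular designs, naming the collinear
  terms; `reduce_model()`'s worst case is the intercept-only model, whose
  F test is reported as undefined under the standard convention rather
  than as a 0/0.
* Ties cannot occur in backward elimination's p-value comparison for
  continuous responses; if they did, `which.max` drops the earlier term
  in the canonical order.

## Limitations

* The second level is a local polynomial in two factors; extrapolation
  beyond the axial radius is flagged but unvalidated, and the design
  provides no lack-of-fit test against pure error (the center replicates
  would support one, but with a single replicate pair its power is
  negligible).
* Confidence bands cover the mean curve, not a new experimental curve.
* For rapidly inactivating enzymes the first-level model is
  mis-specified; the package follows the pragmatic route of fitting it
  anyway and letting the second-level diagnostics (lower $R^2$, inflated
  prediction errors) reveal the problem, rather than switching to an
  inactivation-aware fit.
* The inverse problem — choosing (T, E) to hit a target DH — is only a
  root-find away from `predict_curve()` but is not provided as a
  validated feature.
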