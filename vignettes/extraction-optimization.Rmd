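---
title: "Modeling and optimizing ultrasound-assisted extraction: response surfaces and a PSO-tuned SVR surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing ultrasound-assisted extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaeopt)
```

## The problem

Ultrasound-assisted extraction of plant polysaccharides is governed by a
handful of process settings — sonication time, liquid–solid ratio,
ultrasonic power, bath temperature, and raw-material particle size — whose
joint effect on yield is smooth but interacting. The experimental workhorse
is a Box–Behnken design (BBD): a three-level incomplete factorial that, for
five factors, places 40 runs at edge midpoints (every (±1, ±1) pair
combination with the other factors at their centers) plus replicated center
runs. The replicates estimate pure measurement error; the edge runs support
a full second-order polynomial.

`uaeopt` models such designs two ways and optimizes both surfaces over the
experimental box. The bundled dataset (`rlmp_design()`) is the complete
46-run design, with six center replicates, of a *Rosa laevigata*
polysaccharide study; every worked number below is computed from it at run
time.

## The quadratic response surface

With coded settings $z_i \in [-1, 1]$ (the affine map sending low/center/
high to $-1/0/+1$; the data's level table implies this coding, and
`code_value()`/`decode_value()` implement it exactly), the model is

$$Y = \beta_0 + \sum_i \beta_i z_i + \sum_{i<j} \beta_{ij} z_i z_j +
      \sum_i \beta_{ii} z_i^2 + \varepsilon,
      \qquad \varepsilon \sim N(0, \sigma^2) \text{ i.i.d.}$$

— 21 terms for five factors, fitted by OLS (`fit_quadratic()`). Fitting on
coded units keeps the columns near-orthogonal (for a BBD the linear and
interaction columns are exactly orthogonal to everything else) and the
coefficients scale-comparable. `to_actual_units()` substitutes the coding
map back algebraically, so the actual-unit equation describes the identical
surface; because published equations round their coefficients, small
cancellation errors (a few hundredths of a percent yield near the center)
are expected when evaluating a printed equation rather than the
full-precision refit.

### The ANOVA (`rsm_anova()`)

The decomposition mirrors what Design-Expert reports, which is the lingua
franca of this literature:

* **Per-term partial (Type III) SS** on coded units:
  $SS_j = \hat\beta_j^2 / [(X'X)^{-1}]_{jj}$, each tested with
  $F_j = SS_j / MS_{res}$. On a BBD the linear and interaction terms are
  orthogonal to all other columns, so their partial SS coincide with
  sequential SS; the tests assert this on the bundled design and check the
  partial-SS formula against delete-one-term refits on a 3-factor BBD.
* **Lack of fit vs pure error**: replicate groups (identical coded rows)
  give $SS_{PE}$ with one df fewer than each group size;
  $SS_{LOF} = SS_{res} - SS_{PE}$ and $F = MS_{LOF}/MS_{PE}$. Without
  replicates the rows are omitted and flagged rather than silently
  miscomputed.
* **PRESS and predicted R²** via the hat-matrix identity
  $PRESS = \sum_i (e_i/(1-h_{ii}))^2$ — exact leave-one-out for OLS, no
  refitting loop.
* **Adequacy precision**, a signal-to-noise ratio left undefined in most
  papers; we adopt the Design-Expert definition
  $(\max\hat y - \min\hat y)/\sqrt{p \, MS_{res}/n}$ over the design
  points, which reproduces the conventional values on the bundled data.
* p-values come from the upper tail of the central F distribution and are
  displayed as "< 0.0001" below that threshold, matching the field's
  reporting style; stored values are exact.

### Maximizing the surface

`maximize_quadratic()` runs L-BFGS-B ascent from the $2^5$ cube corners,
the center, and a fixed set of interior points, in coded units with box
constraints. A quadratic in five variables has at most one interior
stationary point, so this deterministic multistart is exhaustive in
practice; using the stochastic swarm here would only add seed dependence to
a result that has none. (`optimize_conditions()` on the same model is a
cross-check — the two agree to hundredths of a percent.)

## The ε-SVR surrogate

The quadratic is an assumption; the surrogate route lets the data speak
with fewer shape constraints. Inputs and yield are min–max normalized to
$[0,1]$ (`fit_bounds()`, `normalize_x()`, `normalize_y()`), and an
ε-insensitive SVR with RBF kernel $K(x,x') = \exp(-\gamma\|x-x'\|^2)$ is
trained by solving the standard dual (box constraints $[0, C]$, one
equality constraint) with a sequential-minimal-optimization solver written
in C++: second-order (maximal guaranteed decrease) working-set selection,
KKT tolerance $10^{-6}$, iteration cap $10^5$. The bias is recovered as the
midpoint of the KKT-feasible interval, which collapses to the usual
free-support-vector average whenever free vectors exist. An independent SVM
implementation (e1071/libsvm) serves as a dual-objective oracle in the test
suite; it is never the implementation.

Numerical choices that matter:

* **ε = 0.01 on the normalized scale** (about 0.05 % yield for the bundled
  data). The tube width is rarely reported in extraction papers; this
  default is small enough that a high-capacity fit can track the surface
  to within replicate noise, and large enough to keep the dual sparse. It
  is exposed everywhere as a parameter.
* **Degenerate targets**: if all training responses are identical the
  constant model is returned directly (no support points) rather than
  exercising the solver on a problem whose solution is known.
* **Full kernel matrix**: designs here have tens of runs, so no caching or
  chunking is warranted.
* Metric definitions (`regression_metrics()`) are the plain
  $R^2 = 1 - \sum(Y_i - Y'_i)^2 / \sum(Y_i - \bar Y)^2$, RMSE and MAE with
  no degrees-of-freedom adjustment. Because the scale of reported SVR
  errors is ambiguous in much of the literature, the tuning report carries
  both raw-percent and normalized metrics with explicit labels.

## Particle swarm optimization

`pso_minimize()` implements the classic inertia-weight update

$$v \leftarrow w v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x),
  \qquad x \leftarrow x + v$$

with $w = 0.8$, $c_1 = c_2 = 2$, 50 particles, 50 iterations by default —
the configuration standard in this application area — and convergence
declared when the global best improves by less than $10^{-4}$ over 10
generations. Decisions where the textbook update leaves latitude:

* $r_1, r_2$ are fresh **scalar** uniforms per particle per iteration (the
  common reading of the update equations); a per-dimension mode is a
  config switch.
* Positions are **clipped to the box** after each move with the clipped
  velocity component zeroed — feasibility without reflection artifacts on
  a small box.
* Velocities are **clamped at half the box width** per dimension; the
  $w = 0.8, c_1 = c_2 = 2$ regime is known to diverge without a clamp.
* Maximization is minimization of the negated objective — one code path.
* Convergence monitors the global-best objective value.

Runs are deterministic for a fixed seed, and the seeded helper restores the
caller's RNG state, so pipelines are reproducible end to end.

## The tuning pipeline

`split_dataset()` shuffles run ids under a seed and assigns the first
round(0.8 n) to training — 37/9 for 46 runs (0.8 × 46 = 36.8 rounds half
up; the conventional "8:2" never states the integer split).
`tune_svr()` minimizes **held-out test RMSE on the normalized scale** over
$(C, \gamma) \in [0.1, 100]^2$ with the PSO above, then refits at the best
candidate and reports train/test/all-run metrics on both scales. Held-out
error is the objective because the train/test split precedes tuning in the
standard workflow narrative; k-fold cross-validation would be a reasonable
alternative and can be emulated by seed lists.

Because tuning is stochastic, `run_full()` accepts a seed list (default
style: ten seeds) and reports the per-seed table with the best and median
highlighted, rather than pretending a single unseeded number is *the*
result.

### A ceiling worth knowing about

With replicated center runs, any deterministic regressor predicts a single
value at the replicated point, so its residual SS on the full dataset is at
least the pure-error SS. For the bundled design that caps the all-46-run
$R^2$ at $1 - 0.1841/74.38 = 0.9975$, a bound the tuned surrogate approaches
but can never cross. Published all-run accuracies above this ceiling cannot
be Eq.-8 coefficients of determination on the full dataset; parity-plot
regression $R^2$ (slope/intercept free) is the usual source of such
numbers, and `compare_models()` reports exactly that quantity alongside the
strict metrics so both conventions are available.

`optimize_conditions()` maximizes the tuned surrogate's raw-scale
prediction over the actual-unit box and `round_practical()` snaps the
result to what a laboratory can set: whole minutes, mL/g and °C, 20 W
power steps, and the standard sieve series 0.25/0.355/0.425/0.6/0.85 mm.

## Assay arithmetic

The assay module is deliberately plain arithmetic with guard rails:
standard-curve inversion $(A - b)/a$; extraction yield
$C \cdot V \cdot d / m \times 100$ with the mg→g conversion made explicit;
scavenging rate $(1 - (A_s - A_b)/A_0) \times 100$. IC50 estimation fits a
four-parameter logistic by Levenberg–Marquardt (on log-EC50 for
stability) and reports the concentration at which the *fitted curve*
crosses 50 % — distinct from the logistic midpoint when the plateaus are
not 0 and 100. If the fit fails, monotone interpolation between the
bracketing points is used and labeled; if responses never cross 50 %, the
IC50 is flagged undefined rather than extrapolated. Published IC50 values
whose underlying absorbance curves exist only as figures are treated as
reference values, never as test assertions.

## Synthetic data and what the tests show

`generate_design_response()` draws a BBD response as quadratic mean plus
i.i.d. Gaussian noise — exactly the assumption the OLS/ANOVA machinery
makes. The default truth is the coded-unit refit of the bundled dataset
and the default noise is its residual standard deviation
($\sqrt{0.0654} \approx 0.26$ % yield), so simulations resemble the study
that motivated the package. `generate_dose_response()` does the same for
4PL curves.

The simulation-based tests use sizes chosen to keep Monte-Carlo error
small relative to the asserted margins: 500 replicates for the null
uniformity of the model-F p-value (Kolmogorov–Smirnov statistic < 0.08)
and for the lack-of-fit size (≤ 10 % rejections at the 5 % level), 200 for
2-SE coefficient coverage (≥ 93 % against a nominal ~95 %), and 100 for
IC50 recovery within 10 % at σ = 2 noise.

What passing these tests does **not** show: real extraction data are not
exactly quadratic, their errors are not exactly Gaussian or homoscedastic,
and run order effects (drift, blocking) are invisible here because the
generator has none. The synthetic route validates the *machinery* —
estimator correctness, test calibration, recovery — not the chemistry.

## Known limitations

* Designs beyond Box–Behnken (central-composite, Plackett–Burman,
  D-optimal) and randomization/blocking schemes are out of scope.
* The SVR is ε-insensitive RBF only; no ν-SVR, linear/polynomial kernels,
  or probabilistic outputs.
* PSO is the plain inertia-weight variant; no constriction factor,
  adaptive schedules, or topologies.
* Plot rendering is intentionally absent — the JSON/CSV exports are the
  interface to external plotting.
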