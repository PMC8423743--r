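---
title: "Interaction regression for county-level crop yield: model, selection and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction regression for county-level crop yield: model, selection and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`interactreg` predicts county-level crop yield (t/ha) from a county-year
panel of weather, soil and management variables with a linear model
augmented by kernel-encoded interactions:

$$
\hat{y}_i \;=\; \beta_0 \;+\; \sum_{j \in \mathcal{P}} X_{ij}\,\beta_j
\;+\; \sum_{m \in \mathcal{M}} b_m\, Z_{im},
$$

where $X$ is the normalized design (every variable min–max scaled to
$[0,1]$ on the training rows), $\mathcal{P}$ the set of selected additive
features, and each interaction variable $Z_{im} = K_{k(m)}(X_{i,a_m},
X_{i,b_m})$ is a fixed bivariate kernel evaluated on a pair of normalized
columns. A term with $a_m = b_m$ is a *self-interaction*; with the product
kernel this is a quadratic effect. Everything stays an ordinary least
squares problem — the nonlinearity lives entirely in the construction of
$Z$, which is what keeps the model dissectable: each prediction splits
exactly into intercept + weather + soil + management + interaction
contributions (`decompose_contributions()`), and partial dependence
profiles of any one or two variables are cheap
(`partial_dependence()`).

### The kernel registry

The default registry carries six bounded, symmetric kernels on the unit
square, chosen to span the qualitative shapes a pair of agronomic factors
can take:

| id        | $K(x,y)$            | shape                              |
|-----------|---------------------|------------------------------------|
| `product` | $xy$                | synergy; $x^2$ on self-pairs       |
| `min`     | $\min(x,y)$         | limiting factor (Liebig)           |
| `max`     | $\max(x,y)$         | either-sufficient                  |
| `sqmean`  | $((x+y)/2)^2$       | joint-level curvature              |
| `absdiff` | $|x-y|$             | imbalance; degenerate on self-pairs |
| `satprod` | $1-(1-x)(1-y)$      | saturating (noisy-or) synergy      |

The registry is data: `register_kernel()` adds user kernels, so an
alternative kernel set can be dropped in without touching the search.
`absdiff` is flagged not self-admissible ($|x-x| \equiv 0$).

A structural fact worth knowing: once both main effects of a pair are in
the model, `satprod` spans the same residual direction as `product`
($1-(1-x)(1-y) = x + y - xy$). The search resolves this deliberately (see
*Tie-breaking* below) instead of letting floating-point jitter decide.

## Selection of robust features and interactions

The search space is large — with $p$ variables there are $p^2$ ordered
pairs including self-pairs (at the production scale of 613 variables,
375,769), each with up to six kernels. Selection proceeds in stages, all
scored by a *spatio-temporal robustness score*: the unweighted mean of the
validation error (RRMSE by default) over a set of blocked folds that mix
two axes,

* **temporal** folds — years are split into `n_folds + 1` contiguous
  blocks; fold *j* validates block *j + 1* and trains on all strictly
  earlier years (an expanding window). Training years always strictly
  precede validation years, so a fold never sees the future. The first
  block is never validated: it has no earlier years to train on, and a
  fold with an empty training side cannot be scored.
* **spatial** folds — leave-one-group-out over user-supplied county
  groups (states, districts, random blocks). A county never appears on
  both sides of a fold.

Normalization is refitted *inside every fold* on its training rows, so no
statistic of the validation rows — not even a column minimum — reaches the
fit.

The stages:

1. **Elastic-net pre-screen per category** (`elastic_net_prescreen()`),
   using glmnet. The $(\alpha, \lambda)$ grid is scored on the same
   blocked folds (mean validation RMSE; ties prefer the sparser solution)
   and the full-data refit at the winning point returns the nonzero
   variables, strongest first, truncated to the per-category cap.
   Categories are screened separately so a dominant category (weather)
   cannot crowd out soil or management before the stepwise stage.
2. **Residual screening.** All candidate terms are ranked by the absolute
   correlation of their column with the current model's training
   residuals, *after projecting $\{1, x_a, x_b\}$ out of the candidate
   column*. Without the projection the statistic is diluted for kernels
   with a large linear part (a raw product column is mostly $x$ and $y$,
   which the model already fits), and is biased toward kernels with no
   linear part. The top `top_screen` terms (default 30) go forward.
3. **Forward stepwise** (`forward_stepwise()`): greedily add the candidate
   with the best aggregate score, while the improvement is at least `tol`
   (default 0.05 RRMSE percentage points) and at most `max_added` per
   cycle.
4. **Backward elimination** (`backward_eliminate()`): repeatedly remove
   the term whose removal most improves (or least degrades, within `tol`)
   the score. `tol = Inf` strips to intercept-only.
5. Steps 2–4 repeat until a full cycle leaves the interaction set
   unchanged or `max_cycles` is reached.

### Strong heredity

By default (`heredity = TRUE`) an interaction term is evaluated and kept
together with the main effects of its two variables. This is the standard
hierarchy principle of interaction selection, and it has a second, very
concrete benefit here: with the mains present, kernels that differ only by
linear parts (`product` vs `satprod`) become *exactly* equivalent in fit,
so the choice between them falls to the deterministic tie-break rather
than to noise.

### Tie-breaking and determinism

Candidates are always processed in canonical order (catalogue index of
`var_a`, then `var_b`, then kernel registration order). Scores within a
relative $10^{-7}$ band count as tied and the canonically first candidate
wins. Together with seed-free deterministic fitting (OLS, glmnet with a
fixed grid) this makes the whole selection a pure function of panel +
folds + config: identical runs serialize byte-identically.

### Degenerate designs

Exactly collinear candidate evaluations are routine inside the stepwise
loop (equivalent kernels, duplicated information), so the fold scorer
falls back to the minimum-norm least-squares solution there without
complaint. At the user-facing level (`fit_model()`,
`robustness_score()`) rank deficiency emits a warning naming the issue;
`n \le` number of coefficients is always a hard error.

## Data model and derived features

Panels are plain CSV: `county_id, year[, yield]`, then variables prefixed
`W_`/`S_`/`M_`, weekly columns suffixed `_wk13`…`_wk52`, soil depths
`_d<label>`. Sub-county grids aggregate with the category's convention —
mean for soil, median for weather (robust to local outliers); management
is county-level by construction.

Derived agronomic features follow standard conventions, since only the
feature names, not formulas, are fixed by common usage:

* daily GDD $=\max\{0, (\min(T_{max}, 30) + \max(T_{min}, 10))/2 - 10\}$
  (base 10 °C, cap 30 °C — the corn convention; both configurable). The
  panel-level `gdd` recipe multiplies the weekly-mean rate by 7.
* rainy day: daily precipitation > 1 mm; heat-unit day: daily
  $T_{max}$ > 30 °C (both thresholds configurable). These need daily
  inputs, so they are exposed as helpers for the aggregation stage rather
  than panel recipes.
* yield-trend covariate: the per-county least-squares line of historical
  yield on year, evaluated at each row's year using **strictly prior
  years only**. The look-ahead restriction is a deliberate anti-leakage
  choice: the covariate must be computable at prediction time for a
  future year.

Normalization is fitted on training rows only and never clipped: a test
year hotter than anything in training maps above 1, which is information,
not an error. Constant columns map to 0 (not dropped) so catalogue
indices stay stable.

## In-season forecasting

One model is fitted pre-season and reused all year. At forecast week $w$
the observed columns (weeks $\le w$, soil, static management) come from
the target county-year; every historical donor year of the county
supplies one completion of the unobserved weeks. Cumulative
planting-progress columns are, by default, rescaled so the donor's
remaining curve continues monotonically from the last observed progress
value (raw donor copy is available via `progress_splice = "copy"`). The
week's forecast is the median of the per-scenario predictions; the band
is the first and third quartiles, computed with linear interpolation
between order statistics (`stats::quantile` type 7) — fixed and
documented so intervals are reproducible. At the final week nothing is
left to splice, every scenario equals the observed row, and the forecast
collapses exactly onto the point prediction.

## The synthetic generator

`generate_panel()` emulates the statistical structure the method assumes,
so selection, fitting, dissection and forecasting are testable without
any data download:

* weekly weather: AR(1) fluctuations around a seasonal sinusoid plus a
  static county offset, per variable type (Tmax, Tmin, Prcp, Srad);
* soil: static per county, a shared profile attenuated with depth plus an
  independent per-depth perturbation (depths are correlated, never
  collinear — exact collinearity would make the design unidentifiable);
* management: logistic planting-progress curves with county-year planting
  dates, plus independent survey/reporting noise per weekly report.
  Without that noise every weekly progress column would be a
  deterministic monotone transform of the same latent planting date, and
  no method could tell which week a planted interaction acts through;
* yield: intercept + planted additive effects + planted kernel
  interactions + per-county linear technology trend + Gaussian noise.

All planted coefficients act on the generator's own normalized scale.
Draws are clamped to fixed per-column bounds at mean ± 2.5 total SD and
those bounds are stored in the ground truth: the normalized design then
lies strictly inside $[0,1]$ and noiseless yields are *exactly*
recomputable from the truth file. This is also why `fit_model()` accepts
a pre-specified scaler: refitting OLS in the generator's own coordinates
recovers the planted coefficients to machine precision at
$\sigma = 0$, a sharp end-to-end correctness check. With an estimated
scaler the design is an affine distortion of the truth and recovery is
only asymptotic — that case is covered by the stochastic tests.

The **reference scenario** (shipped as
`inst/extdata/reference_scenario.json`) is 50 counties × 20 years
(1000 rows), 40 weekly weather + 10 soil + 5 management variables, five
additive effects, and two planted product interactions — one
weather×weather, one weather×management — with coefficients 2.0 and −1.6
t/ha against yield noise $\sigma = 0.3$ t/ha ($|b|/\sigma \ge 3$). The
coefficient scale was set by a power argument made *before* looking at
outcomes: with main effects in the model, the detectable part of a
product term is its doubly-centred component, whose standard deviation is
roughly $b \cdot \mathrm{sd}(x)\,\mathrm{sd}(y) \approx 0.04\,b$ here, so
$b$ of order 2 puts the interaction signal safely above the validation
noise floor at $n = 1000$ while the coefficient-to-noise ratio stays
within the scenario's stated regime.

What the generator does **not** emulate: spatial correlation between
neighbouring counties, weather extremes and skewness, missingness, and
any crop physiology (that is the role of process models like APSIM or
DSSAT). Passing the recovery benchmark therefore shows the selection
machinery works under the model's own assumptions — it does not certify
performance on real panels, where kernel misspecification and correlated
noise are the dominant risks.

## Problem sizes and runtime choices

The shipped tests run the reference scenario (1000 rows, 55 variables,
≈ 9,000 deduplicated candidate terms, 9 blocked folds) through the full
pipeline in a few seconds per seed; the recovery benchmark repeats it
over 100 seeds. The unit-test fixtures use a reduced scale (10 counties ×
10 years) where a property does not need the reference size. These sizes
are the package's own benchmark design: large enough that recovery and
error rates are stable, small enough to iterate on.

## Known limitations

* The stepwise search is greedy: it carries no global-optimality
  guarantee, and the oracle-equivalence test covers only the orthogonal
  regime where greedy provably coincides with best-subset.
* Kernels are evaluated on min–max normalized inputs, so the fitted
  interaction surface depends (mildly) on the training-window scaling.
* The forecast ensemble treats donor years as exchangeable completions;
  it carries no weighting by climatological similarity.
* Only two-way interactions are searched; higher-order structure is out
  of scope by design.
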