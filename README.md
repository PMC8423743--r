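# interactreg

Interaction regression for county-level crop yield prediction.

County-year yield (t/ha) is notoriously shaped not only by weather, soil
and management individually, but by their joint — environment × management
(E×M) — effects: the same planting date means something different in a
cold April than in a warm one. `interactreg` models this with a linear
regression augmented by *kernel-encoded* interactions,

$$\hat{y}_i = \beta_0 + \sum_{j \in \mathcal{P}} X_{ij}\,\beta_j
  + \sum_{m \in \mathcal{M}} b_m\, Z_{im}, \qquad
  Z_{im} = K_{k(m)}\!\left(X_{i,a_m}, X_{i,b_m}\right),$$

where $X$ is the min–max normalized design and each interaction column is
a fixed bivariate kernel (product, min, max, squared mean, absolute
difference, saturating product) of two variables; a term with
$a_m = b_m$ is a quadratic self-interaction. The features $\mathcal{P}$
and interactions $\mathcal{M}$ are selected for *spatio-temporal
robustness*: an elastic-net pre-screen per category, then a
forward/backward stepwise search scored by the mean validation error
across blocked folds that span different year blocks (temporal axis) and
different county groups (spatial axis). Because the final model is plain
OLS, every prediction dissects exactly into intercept + weather + soil +
management + interaction contributions, and in-season forecasts come from
an ensemble of historical weather completions.

The package is aimed at quantitative agronomists and forecasting groups
working with county-year panels (e.g. NASS-style yield data joined with
mesonet weather and soil survey attributes). It ships a synthetic panel
generator with planted ground truth, so the entire pipeline is testable
and benchmarkable offline.

## Worked example

Simulate the reference scenario (50 counties × 20 years, 55 variables,
two planted product interactions), search on the years before 2017, and
evaluate on the held-out year:

```r
library(interactreg)

gen <- generate_panel(reference_synth_config(seed = 7))
panel <- gen$panel
panel
#> sample_panel: 1000 rows (50 counties, years 1998-2017), 55 variables
#>   weather 40 | soil 10 | management 5 | yield: present | natural units

train <- subset_panel(panel, which(panel$rows$year < 2017))
groups <- setNames(rep(sprintf("g%d", 1:5), each = 10), sprintf("c%03d", 1:50))
folds <- combine_folds(make_folds(train, "temporal_kblock", n_folds = 4),
                       make_folds(train, "spatial_holdout", groups = groups))

sel <- search_robust_interactions(train, folds)
sel
#> selection_result: 24 features, 2 interaction terms
#>   terms: W_tmax_wk25:W_prcp_wk23:product, W_tmin_wk21:M_planted_wk22:product

fit <- fit_model(train, sel$features, sel$terms)
test <- subset_panel(panel, which(panel$rows$year == 2017))
round(evaluate_metrics(test$y, predict(fit, test)), 3)
#>  RMSE RRMSE   RSE   MAE   RAE    R2
#> 0.284 4.342 0.210 0.228 0.464 0.790
```

Both planted interactions were recovered exactly (variable pair and
kernel); the held-out RMSE of 0.284 t/ha sits at the generator's noise
floor (σ = 0.3). Each prediction splits into additive contributions that
sum exactly to the predicted yield:

```r
head(decompose_contributions(fit, test), 3)
#>   intercept weather  soil management interaction total
#> 1     6.119  -0.387 0.559     -0.182       0.864 6.973
#> 2     6.119   0.470 0.458     -0.287      -0.846 5.913
#> 3     6.119   0.150 1.173      0.037       0.092 7.569
```

In-season forecasting splices the weather observed through week *w* with
historical completions; the band is the interquartile range over donor
scenarios and collapses onto the point prediction once everything is
observed:

```r
target  <- subset_panel(panel, which(panel$rows$county_id == "c007" &
                                     panel$rows$year == 2017))
history <- subset_panel(panel, which(panel$rows$county_id == "c007" &
                                     panel$rows$year < 2017))
season_forecast(fit, target, history, weeks = c(21, 24, 27, 29))
#>   week median    q1    q3 n_scenarios
#> 1   21  6.826 6.270 7.022          19
#> 2   24  7.381 7.234 7.622          19
#> 3   27  7.450 7.436 7.465          19
#> 4   29  7.445 7.445 7.445          19
```

A command-line front end wraps the same pipeline
(`exec/interactreg <simulate|fit|predict|evaluate|decompose|forecast>
--config cfg.yaml [--seed N] [--out DIR]`), with YAML configs, JSON/CSV
artifacts and a config echo next to every output.

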