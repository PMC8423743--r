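# shared fixtures, all built in code

## minimal hand-made panel: 4 rows, one variable per category
tiny_panel <- function(y = c(8, 9, 10, 11)) {
  X <- cbind(W_prcp_wk20 = c(10, 20, 30, 40),
             S_om_d5 = c(2, 3, 4, 5),
             M_planted_wk20 = c(0.1, 0.4, 0.7, 0.9))
  sample_panel(county_id = c("adams", "adams", "boone", "boone"),
               year = c(2001, 2002, 2001, 2002), X = X, y = y)
}

## reduced-scale generator config for fast unit tests
small_synth <- function(seed = 1L, ...) {
  synth_config(n_counties = 10L, years = 2008:2017,
               weather_weeks = 20:24, progress_weeks = 20:22,
               beta = c(W_tmax_wk22 = -1.2, W_prcp_wk21 = 0.9,
                        S_om_d0_5 = 1.1),
               interactions = list(
                 list(var_a = "W_prcp_wk21", var_b = "W_tmax_wk23",
                      kernel_id = "product", b = 2.0)),
               seed = seed, ...)
}

## default study folds: expanding temporal blocks + leave-one-group-out
study_folds <- function(panel, n_temporal = 4L, n_groups = 5L) {
  counties <- sort(unique(panel$rows$county_id))
  groups <- stats::setNames(
    rep(sprintf("g%d", seq_len(n_groups)), length.out = length(counties)),
    counties)
  combine_folds(make_folds(panel, "temporal_kblock", n_folds = n_temporal),
                make_folds(panel, "spatial_holdout", groups = groups))
}

expect_panel_equal <- function(a, b) {
  expect_identical(a$rows, b$rows)
  expect_equal(a$X, b$X)
  expect_equal(a$y, b$y)
  expect_identical(a$catalogue$name, b$catalogue$name)
}
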