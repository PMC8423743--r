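test_that("panel CSV round-trips cell-identically and infers the catalogue", {
  p <- tiny_panel()
  expect_equal(catalogue_counts(p$catalogue),
               c(weather = 1L, soil = 1L, management = 1L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- load_panel(f)
  expect_panel_equal(p, p2)
  ## and the files themselves round-trip
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed panel inputs fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("county_id,year,yield,W_prcp_wk20",
               "adams,2015,9.1,12", "adams,2015,9.3,14"), f)
  expect_error(load_panel(f), "adams/2015")
  writeLines(c("county_id,year,yield,Q_bogus",
               "adams,2015,9.1,12"), f)
  expect_error(load_panel(f), "Q_bogus")
  writeLines(c("county_id,year,yield,W_prcp_wk20",
               "adams,2015,9.1,oops"), f)
  expect_error(load_panel(f), "row 1.*W_prcp_wk20")
  writeLines("county_id,year,yield,W_prcp_wk20", f)
  expect_error(load_panel(f), "no data rows")
  expect_error(variable_catalogue("W_x_wk60", "weather", week = 60L),
               "week_index")
})

test_that("county aggregation is mean for soil, median for weather", {
  expect_equal(aggregate_to_county(c(1, 2, 3), "soil"), 2)
  expect_equal(aggregate_to_county(c(1, 2, 100), "weather"), 2)
  expect_error(aggregate_to_county(numeric(0), "weather"), "empty")
  expect_error(aggregate_to_county(c(1, NaN), "soil"), "non-finite")
  expect_error(aggregate_to_county(5, "management"), "county-level")
})

test_that("derived agronomic features follow the documented formulas", {
  expect_equal(gdd_daily(30, 10), 10)              # ((30+10)/2 - 10)
  expect_equal(gdd_daily(35, 10, cap = 30), 10)    # Tmax capped at 30
  expect_equal(gdd_daily(15, 2), 2.5)              # Tmin floored at base
  expect_equal(gdd_daily(5, 0), 0)                 # never negative
  expect_equal(count_rainy_days(c(0, 2, 5, 0.2)), 2)
  expect_equal(count_heat_units(c(31, 29, 35, 30)), 2)
})

test_that("yield-trend covariate extrapolates the strictly-prior OLS line", {
  X <- cbind(W_tmax_wk20 = c(25, 26), W_tmin_wk20 = c(12, 10))
  p <- sample_panel(c("adams", "adams"), c(2004, 2005), X, y = c(11, 11.5))
  hist <- data.frame(county_id = "adams", year = 2001:2004,
                     yield = c(8, 9, 10, 25))  # 2004 must not leak into 2004
  p2 <- derive_features(p, c("gdd", "yield_trend"), history = hist)
  tr <- p2$X[, "M_yield_trend"]
  expect_equal(tr[1], 11)  # line through (2001,8),(2002,9),(2003,10) at 2004
  ## GDD column appended, original columns byte-identical
  expect_true("W_gdd_wk20" %in% colnames(p2$X))
  expect_equal(p2$X[, "W_gdd_wk20"], 7 * gdd_daily(c(25, 26), c(12, 10)),
               ignore_attr = TRUE)
  expect_identical(p2$X[, colnames(p$X)], p$X)
  ## too little history errors with the county named
  expect_error(derive_features(p, "yield_trend",
                               history = hist[hist$year >= 2003, ]),
               "adams")
})

test_that("min-max scaler maps fit rows to [0,1], never clips, inverts", {
  X <- cbind(W_a_wk20 = c(2, 4, 6, 8), S_b_d5 = c(5, 5, 5, 7))
  p <- sample_panel(c("a", "a", "b", "b"), c(2001, 2002, 2001, 2002), X)
  sc <- fit_scaler(p, fit_rows = 1:3)
  np <- apply_scaler(p, sc)
  expect_equal(unname(np$X[1:3, "W_a_wk20"]), c(0, 0.5, 1))
  expect_equal(unname(np$X[4, "W_a_wk20"]), 1.5)   # outside fit range
  expect_equal(unname(np$X[1:3, "S_b_d5"]), c(0, 0, 0))  # constant -> 0
  expect_true(np$normalized)
  expect_equal(invert_scaler(np$X[, "W_a_wk20"], sc, "W_a_wk20"),
               unname(X[, "W_a_wk20"]))
})

test_that("fold schemes satisfy the blocking invariants", {
  yrs <- rep(1990:2017, each = 2)
  X <- cbind(W_a_wk20 = seq_along(yrs))
  p <- sample_panel(rep(c("a", "b"), length(yrs) / 2), yrs, X)
  fs <- make_folds(p, "temporal_kblock", n_folds = 4)
  expect_length(fs, 4L)
  for (f in fs) {
    expect_gt(length(f$validation), 0)
    expect_length(intersect(f$train, f$validation), 0)
    expect_lt(max(p$rows$year[f$train]), min(p$rows$year[f$validation]))
    ## validation blocks are contiguous year runs
    vy <- sort(unique(p$rows$year[f$validation]))
    expect_equal(vy, seq(min(vy), max(vy)))
  }
  ## chronological fold order, expanding training window
  starts <- vapply(fs, function(f) min(p$rows$year[f$validation]), numeric(1))
  expect_equal(starts, sort(starts))

  fs2 <- make_folds(p, "leave_year_out")
  expect_length(fs2, length(unique(yrs)) - 1L)
  expect_equal(sort(unique(p$rows$year[fs2[[1]]$validation])), 1991)

  groups <- c(a = "east", b = "west")
  fs3 <- make_folds(p, "spatial_holdout", groups = groups, holdout = "west")
  expect_length(fs3, 1L)
  expect_setequal(unique(p$rows$county_id[fs3[[1]]$validation]), "b")
  expect_length(intersect(p$rows$county_id[fs3[[1]]$train],
                          p$rows$county_id[fs3[[1]]$validation]), 0)

  expect_error(make_folds(p, "temporal_kblock", n_folds = 40), "distinct")
})

test_that("fold scheme exports as JSON with both axes", {
  g <- generate_panel(small_synth())
  fs <- study_folds(g$panel, n_groups = 2L)
  f <- withr::local_tempfile(fileext = ".json")
  write_folds(fs, f)
  j <- jsonlite::read_json(f)
  expect_length(j, length(fs))
  expect_setequal(unique(vapply(j, `[[`, character(1), "axis")),
                  c("temporal", "spatial"))
})
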