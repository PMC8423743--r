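test_that("hand-evaluated prediction: intercept + beta x + b z", {
  ## beta0 = 1, one feature X = 0.5 with beta = 2, one product interaction
  ## with Z = 0.5 * 0.4 = 0.2 and b = 3: yhat = 1 + 1.0 + 0.6 = 2.6
  X <- cbind(W_a_wk20 = c(0.5, 1, 0, 0.25),
             W_b_wk20 = c(0.5, 1, 0, 0.75),
             W_c_wk20 = c(0.4, 0, 1, 0.1))
  p <- sample_panel(letters[1:4], rep(2001, 4), X)
  p$normalized <- TRUE
  tm <- interaction_term("W_b_wk20", "W_c_wk20", "product")
  p$y <- 1 + 2 * X[, 1] + 3 * X[, 2] * X[, 3]
  fit <- fit_model(p, features = "W_a_wk20", terms = list(tm))
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  row1 <- subset_panel(p, 1L)
  expect_equal(predict(fit, row1), 2.6, tolerance = 1e-10)
  ## intercept-only model predicts the constant beta0
  p9 <- p; p9$y <- rep(9, 4)
  fit9 <- fit_model(p9)
  expect_equal(fit9$intercept, 9)
  expect_equal(predict(fit9, p), rep(9, 4))
})

test_that("intercept-only OLS returns the mean yield", {
  p <- tiny_panel(y = c(8, 9, 10, 11))
  fit <- fit_model(p)
  expect_equal(fit$intercept, mean(p$y))
})

test_that("noiseless synthetic data is recovered exactly", {
  cfg <- small_synth(seed = 3)
  cfg$noise_sd <- 0
  g <- generate_panel(cfg)
  fit <- fit_model(g$panel, names(cfg$beta),
                   terms_from_list(cfg$interactions),
                   scaler = g$truth$scaler)
  expect_equal(fit$intercept, cfg$beta0, tolerance = 1e-8)
  expect_equal(fit$beta[names(cfg$beta)], cfg$beta, tolerance = 1e-8)
  expect_equal(unname(fit$b), vapply(cfg$interactions, `[[`, numeric(1), "b"),
               tolerance = 1e-8)
})

test_that("duplicated design columns warn and still yield finite fits", {
  p <- tiny_panel()
  expect_warning(fit <- fit_model(p, features = c("W_prcp_wk20",
                                                  "W_prcp_wk20")),
                 "rank deficient")
  expect_true(all(is.finite(unlist(fit$beta))))
  expect_error(fit_model(subset_panel(tiny_panel(), 1:2),
                         features = colnames(tiny_panel()$X)),
               "cannot identify")
})

test_that("metrics match hand computation and their identities", {
  m <- evaluate_metrics(c(2, 4), c(1, 5))
  expect_equal(unname(m["RMSE"]), 1)
  expect_equal(unname(m["RRMSE"]), 100 / 3, tolerance = 1e-12)  # 33.33 %
  expect_equal(unname(m["MAE"]), 1)
  ## perfect prediction
  mp <- evaluate_metrics(c(2, 4), c(2, 4))
  expect_equal(unname(mp["RMSE"]), 0)
  expect_equal(unname(mp["R2"]), 1)
  ## predicting the mean: RSE 1, R2 0
  mm <- evaluate_metrics(c(2, 4, 6), rep(4, 3))
  expect_equal(unname(mm["RSE"]), 1)
  expect_equal(unname(mm["R2"]), 0)
  expect_equal(unname(mm["RAE"]), 1)
  ## identities on random vectors
  set.seed(42)
  for (i in 1:50) {
    y <- rnorm(20, 10, 2); yh <- y + rnorm(20)
    mi <- evaluate_metrics(y, yh)
    expect_equal(unname(mi["R2"]), unname(1 - mi["RSE"]), tolerance = 1e-12)
    expect_equal(unname(mi["RRMSE"] / 100 * mean(y)), unname(mi["RMSE"]),
                 tolerance = 1e-12)
  }
  expect_error(evaluate_metrics(numeric(0), numeric(0)), "nonempty")
  expect_error(evaluate_metrics(c(3, 3), c(1, 2), "R2"), "zero variance")
})

test_that("contribution breakdown conserves the prediction per sample", {
  g <- generate_panel(small_synth(seed = 5))
  sel_f <- c("W_tmax_wk22", "W_prcp_wk21", "S_om_d0_5", "M_planted_wk21")
  tms <- list(interaction_term("W_prcp_wk21", "W_tmax_wk23", "product"),
              interaction_term("S_om_d5_10", "S_om_d5_10", "product"))
  fit <- fit_model(g$panel, sel_f, tms)
  bd <- decompose_contributions(fit, g$panel)
  pred <- predict(fit, g$panel)
  expect_equal(bd$total, pred, tolerance = 1e-10)
  expect_equal(bd$intercept + bd$weather + bd$soil + bd$management +
                 bd$interaction, pred, tolerance = 1e-10)
  ## model with only soil features: other components identically zero
  fit_s <- fit_model(g$panel, c("S_om_d0_5", "S_clay_d0_5"))
  bd_s <- decompose_contributions(fit_s, g$panel)
  expect_equal(bd_s$weather, rep(0, nrow(bd_s)))
  expect_equal(bd_s$management, rep(0, nrow(bd_s)))
  expect_equal(bd_s$interaction, rep(0, nrow(bd_s)))
})

test_that("OLS residuals are orthogonal to the design on training data", {
  g <- generate_panel(small_synth(seed = 6))
  feats <- c("W_tmax_wk22", "W_prcp_wk21", "S_om_d0_5")
  tms <- list(interaction_term("W_prcp_wk21", "W_tmax_wk23", "product"))
  fit <- fit_model(g$panel, feats, tms)
  np <- apply_scaler(g$panel, fit$scaler)
  D <- cbind(1, np$X[, feats], build_interaction_matrix(np, tms))
  r <- g$panel$y - predict(fit, g$panel)
  expect_lt(max(abs(crossprod(D, r))) / nrow(D), 1e-6)
})

test_that("coefficient recovery error shrinks with sample size", {
  rmse_at_n <- function(n_years) {
    cfg <- small_synth(seed = 11)
    cfg$years <- seq(2018 - n_years, 2017)
    g <- generate_panel(cfg)
    fit <- fit_model(g$panel, names(cfg$beta),
                     terms_from_list(cfg$interactions),
                     scaler = g$truth$scaler)
    sqrt(mean((fit$beta[names(cfg$beta)] - cfg$beta)^2))
  }
  errs <- c(rmse_at_n(5), rmse_at_n(20), rmse_at_n(80))
  expect_true(errs[3] < errs[1])  # ~1/sqrt(n) trend
})

test_that("partial dependence reflects the model's functional form", {
  g <- generate_panel(small_synth(seed = 7))
  ## additive-only model: PD is linear in the grid with slope beta
  fit_a <- fit_model(g$panel, "W_tmax_wk22")
  pd <- partial_dependence(fit_a, g$panel, "W_tmax_wk22", grid = c(0, 0.5, 1))
  slopes <- diff(pd$pd) / diff(pd$value_1)
  expect_equal(slopes[1], slopes[2], tolerance = 1e-10)
  expect_equal(slopes[1], unname(fit_a$beta["W_tmax_wk22"]),
               tolerance = 1e-10)
  ## product interaction: PD over x is b * x * mean(y_col) + additive parts
  tm <- interaction_term("W_prcp_wk21", "W_tmax_wk23", "product")
  fit_i <- fit_model(g$panel, character(0), list(tm))
  npi <- apply_scaler(g$panel, fit_i$scaler)
  grid <- c(0.2, 0.8)
  pd_i <- partial_dependence(fit_i, g$panel, "W_prcp_wk21", grid = grid)
  expected <- fit_i$intercept +
    unname(fit_i$b) * grid * mean(npi$X[, "W_tmax_wk23"])
  expect_equal(pd_i$pd, expected, tolerance = 1e-10)
  ## two-variable PD on an additive-only model is separable
  fit_2 <- fit_model(g$panel, c("W_tmax_wk22", "S_om_d0_5"))
  pd2 <- partial_dependence(fit_2, g$panel, c("W_tmax_wk22", "S_om_d0_5"),
                            grid = list(c(0, 1), c(0, 1)))
  v <- matrix(pd2$pd, 2, 2)  # grid1 varies fastest
  expect_equal(v[2, 2] - v[1, 2], v[2, 1] - v[1, 1], tolerance = 1e-10)
  expect_error(partial_dependence(fit_2, g$panel, "W_nope"), "W_nope")
})

test_that("model serialization round-trips and guards the schema", {
  g <- generate_panel(small_synth(seed = 8))
  tms <- list(interaction_term("W_prcp_wk21", "W_tmax_wk23", "product"))
  fit <- fit_model(g$panel, c("W_tmax_wk22", "S_om_d0_5"), tms,
                   metadata = list(train_years = c(2008, 2017)))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  fit2 <- read_model(f)
  expect_equal(predict(fit2, g$panel), predict(fit, g$panel),
               tolerance = 1e-12)
  expect_equal(fit2$beta, fit$beta)
  expect_equal(unname(fit2$b), unname(fit$b))
  ## a panel with a different schema is refused
  other <- tiny_panel()
  expect_error(predict(fit2, other), "schema")
})
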