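test_that("robustness aggregate is the mean of per-fold errors", {
  g <- generate_panel(small_synth(seed = 1))
  folds <- study_folds(g$panel, n_temporal = 3L, n_groups = 2L)
  rep1 <- robustness_score(c("W_tmax_wk22", "W_prcp_wk21"), list(),
                           g$panel, folds)
  expect_length(rep1$per_fold, 5L)
  expect_equal(rep1$aggregate, mean(rep1$per_fold))
  expect_setequal(unique(rep1$axes), c("temporal", "spatial"))
  ## single fold: aggregate equals that fold's value
  rep2 <- robustness_score("W_tmax_wk22", list(), g$panel,
                           make_folds(g$panel, "leave_year_out")[1])
  expect_equal(rep2$aggregate, unname(rep2$per_fold[1]))
})

test_that("a model that predicts validation yields exactly scores zero", {
  ## yields are an exact linear function of one column: every fold fits it
  v <- seq(10, 120, by = 10)
  X <- cbind(W_prcp_wk20 = v)
  p <- sample_panel(rep(letters[1:4], 3), rep(2001:2003, each = 4), X,
                    y = 2 + 0.1 * v)
  folds <- make_folds(p, "leave_year_out")
  rep0 <- robustness_score("W_prcp_wk20", list(), p, folds)
  expect_equal(rep0$aggregate, 0, tolerance = 1e-10)
})

test_that("fold fits never touch validation rows", {
  g <- generate_panel(small_synth(seed = 2))
  panel <- g$panel
  folds <- make_folds(panel, "temporal_kblock", n_folds = 3)
  f <- folds[[2]]
  feats <- c("W_tmax_wk22", "W_prcp_wk21")
  rep_a <- robustness_score(feats, list(), panel, folds[2])
  ## dual route: fit on the training rows only, by hand, and evaluate
  tr <- subset_panel(panel, f$train)
  va <- subset_panel(panel, f$validation)
  sc <- fit_scaler(panel, f$train)
  fit <- fit_model(tr, feats, scaler = sc)
  by_hand <- evaluate_metrics(va$y, predict(fit, va), "RRMSE")
  expect_equal(rep_a$aggregate, unname(by_hand), tolerance = 1e-10)
  ## corrupting validation yields must not change the fitted model side:
  panel2 <- panel
  panel2$y[f$validation] <- panel2$y[f$validation] + 5
  fit2 <- fit_model(subset_panel(panel2, f$train), feats, scaler = sc)
  expect_equal(fit2$beta, fit$beta)
})

test_that("elastic-net prescreen finds a planted signal among noise", {
  hits <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    cfg <- small_synth(seed = 100 + s)
    cfg$beta <- c(W_tmax_wk22 = 1.0)
    cfg$interactions <- list()
    cfg$noise_sd <- 0.1
    g <- generate_panel(cfg)
    folds <- make_folds(g$panel, "temporal_kblock", n_folds = 3)
    sel <- elastic_net_prescreen(g$panel, "weather", folds)
    if ("W_tmax_wk22" %in% sel) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("prescreen honours degenerate inputs and the cap contract", {
  g <- generate_panel(small_synth(seed = 3))
  folds <- make_folds(g$panel, "temporal_kblock", n_folds = 3)
  p0 <- g$panel
  p0$y <- rep(8, n_samples(p0))
  expect_identical(elastic_net_prescreen(p0, "weather", folds), character(0))
  sel3 <- elastic_net_prescreen(g$panel, "weather", folds, cap = 3)
  expect_lte(length(sel3), 3L)
  p_noy <- g$panel; p_noy$y <- NULL
  expect_error(elastic_net_prescreen(p_noy, "weather", folds), "yields")
})

test_that("forward stepwise is greedy, tolerance-gated and deterministic", {
  g <- generate_panel(small_synth(seed = 4))
  folds <- study_folds(g$panel, n_temporal = 3L, n_groups = 2L)
  cands <- list("W_tmax_wk22", "W_prcp_wk21", "S_om_d0_5", "W_srad_wk20")
  ## max_added = 0 is the identity
  r0 <- forward_stepwise(cands, selection_result(), g$panel, folds,
                         max_added = 0)
  expect_length(r0$features, 0L)
  r2 <- forward_stepwise(cands, selection_result(), g$panel, folds,
                         tol = 0.05, max_added = 2)
  expect_lte(length(r2$features), 2L)
  ## accepted steps improve the aggregate score monotonically
  expect_true(all(diff(r2$trajectory$score) < 0) ||
                nrow(r2$trajectory) <= 1L)
  ## determinism
  r2b <- forward_stepwise(cands, selection_result(), g$panel, folds,
                          tol = 0.05, max_added = 2)
  expect_identical(r2$features, r2b$features)
})

test_that("pure-noise candidates are not added at a meaningful tolerance", {
  added <- 0L
  for (s in 1:5) {
    cfg <- small_synth(seed = 200 + s)
    cfg$beta <- c(W_tmax_wk22 = 1.0)
    cfg$interactions <- list()
    g <- generate_panel(cfg)
    folds <- study_folds(g$panel, n_temporal = 3L, n_groups = 2L)
    ## candidates unrelated to the generated signal
    cands <- list("W_srad_wk20", "W_prcp_wk24", "S_clay_d30_45")
    r <- forward_stepwise(cands, selection_result(features = "W_tmax_wk22"),
                          g$panel, folds, tol = 0.5)
    added <- added + length(r$features) - 1L
  }
  expect_lte(added, 1L)
})

test_that("backward elimination prunes noise and respects its contract", {
  g <- generate_panel(small_synth(seed = 5))
  folds <- study_folds(g$panel, n_temporal = 3L, n_groups = 2L)
  ## empty input stays empty
  r_empty <- backward_eliminate(selection_result(), g$panel, folds)
  expect_length(r_empty$features, 0L)
  ## tol = Inf strips everything down to intercept-only
  start <- selection_result(
    features = c("W_tmax_wk22", "W_prcp_wk21"),
    terms = list(interaction_term("W_prcp_wk21", "W_tmax_wk23", "product")))
  r_inf <- backward_eliminate(start, g$panel, folds, tol = Inf)
  expect_length(r_inf$features, 0L)
  expect_length(r_inf$terms, 0L)
  ## result is always a subset of the input
  r <- backward_eliminate(start, g$panel, folds, tol = 0.05)
  expect_true(all(r$features %in% start$features))
  ## a planted signal survives while pure noise terms are dropped
  drops <- 0L
  for (s in 1:5) {
    gi <- generate_panel(small_synth(seed = 300 + s))
    fi <- study_folds(gi$panel, n_temporal = 3L, n_groups = 2L)
    st <- selection_result(
      features = c(names(small_synth()$beta), "W_srad_wk24"))
    ri <- suppressWarnings(backward_eliminate(st, gi$panel, fi, tol = 0.05))
    if (!"W_srad_wk24" %in% ri$features) drops <- drops + 1L
  }
  expect_gte(drops, 4L)
})

test_that("greedy forward selection matches exhaustive best-2-subset on
           orthogonal planted signals", {
  matches <- 0L
  n_inst <- 5L
  for (s in seq_len(n_inst)) {
    set.seed(400 + s)
    n <- 120L
    M <- scale(matrix(rnorm(n * 6), n, 6), scale = FALSE)
    Q <- qr.Q(qr(M))  # centred orthonormal columns
    X <- Q * 2 + 0.5  # per-column affine keeps the fit identical
    colnames(X) <- sprintf("W_v%d_wk20", 1:6)
    p <- sample_panel(rep(sprintf("c%02d", 1:10), each = 12),
                      rep(rep(2001:2012, each = 1), 10), X)
    p$y <- 9 + 3 * Q[, 2] + 2 * Q[, 5] + rnorm(n, 0, 0.1)
    folds <- make_folds(p, "temporal_kblock", n_folds = 3)
    cands <- as.list(colnames(X))
    greedy <- forward_stepwise(cands, selection_result(), p, folds,
                               tol = 0, max_added = 2)
    best <- Inf; best_set <- NULL
    for (pair in utils::combn(colnames(X), 2, simplify = FALSE)) {
      sc <- robustness_score(pair, list(), p, folds)$aggregate
      if (sc < best) { best <- sc; best_set <- pair }
    }
    g_sc <- robustness_score(greedy$features, list(), p, folds)$aggregate
    if (isTRUE(all.equal(g_sc, best, tolerance = 1e-9))) matches <- matches + 1L
  }
  expect_identical(matches, n_inst)
})

test_that("the full search recovers planted interactions and stays empty
           under the null", {
  ## reduced-scale version of the reference recovery experiment
  rec <- fdr <- numeric(0)
  for (s in 1:3) {
    g <- generate_panel(reference_synth_config(seed = 500 + s))
    folds <- study_folds(g$panel)
    sel <- search_robust_interactions(g$panel, folds)
    sc <- score_recovery(g$truth, sel)
    rec <- c(rec, sc$recall); fdr <- c(fdr, sc$fdr)
  }
  expect_gte(mean(rec), 0.75)
  expect_lte(mean(fdr), 0.25)
  ## null scenario: no planted interactions
  null_hits <- 0L
  for (s in 1:3) {
    cfg <- reference_synth_config(seed = 600 + s)
    cfg$interactions <- list()
    g0 <- generate_panel(cfg)
    sel0 <- search_robust_interactions(g0$panel, study_folds(g0$panel))
    null_hits <- null_hits + length(sel0$terms)
  }
  expect_lte(null_hits, 1L)
})

test_that("search with max_cycles = 0 returns the prescreen only, and the
           result serializes deterministically", {
  g <- generate_panel(small_synth(seed = 6))
  folds <- study_folds(g$panel, n_temporal = 3L, n_groups = 2L)
  cfg0 <- selection_config(max_cycles = 0L)
  sel0 <- search_robust_interactions(g$panel, folds, config = cfg0)
  expect_length(sel0$terms, 0L)
  expect_gt(length(sel0$features), 0L)
  ## byte-identical serialization across identical runs
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  cfg1 <- selection_config(max_cycles = 1L, top_screen = 10L)
  ## 10 counties x county-level soil columns: the full-panel refit inside
  ## the search is legitimately rank deficient, handled by the min-norm fit
  write_selection(
    suppressWarnings(search_robust_interactions(g$panel, folds,
                                                config = cfg1)),
    f1, g$panel$catalogue)
  write_selection(
    suppressWarnings(search_robust_interactions(g$panel, folds,
                                                config = cfg1)),
    f2, g$panel$catalogue)
  expect_identical(readLines(f1), readLines(f2))
})
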