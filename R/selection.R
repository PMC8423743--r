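#' Selection configuration
#'
#' Knobs of the robust feature/interaction search. Defaults are chosen for
#' county-year panels on the order of 10^3 rows and 10^1-10^2 variables.
#'
#' @param top_screen candidates kept per cycle by the residual-correlation
#'   screen before the stepwise search.
#' @param tol minimum improvement of the aggregate validation score (in
#'   metric units, e.g. RRMSE percentage points) required to accept a forward
#'   addition; also the maximum tolerated worsening for a backward removal.
#' @param max_cycles maximum explore/cross-validate cycles.
#' @param max_added maximum forward additions per cycle.
#' @param caps per-category caps for the elastic-net pre-screen (named
#'   vector; weather is deliberately generous).
#' @param alpha_grid elastic-net mixing values searched.
#' @param nlambda length of the penalty path searched per alpha.
#' @param allow_self allow self-interactions (quadratic effects).
#' @param pair_filter optional category filter, see [enumerate_candidates()].
#' @param heredity when `TRUE` (default), an interaction term is always
#'   evaluated and kept together with the main effects of its two variables
#'   (strong heredity). This makes kernels that differ only by linear parts
#'   exactly equivalent during scoring, so the canonical tie-break — not
#'   numerical jitter — decides between them.
#' @param metric robustness metric: `"RRMSE"` (default), `"RMSE"` or
#'   `"MAE"`; lower is better.
#' @param seed integer echoed into results for provenance.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(top_screen = 30L, tol = 0.05, max_cycles = 5L,
                             max_added = 10L,
                             caps = c(weather = 160L, soil = 40L,
                                      management = 12L),
                             alpha_grid = c(0.1, 0.5, 0.9), nlambda = 50L,
                             allow_self = TRUE, pair_filter = NULL,
                             heredity = TRUE, metric = "RRMSE", seed = 1L) {
  stopifnot(tol >= 0, top_screen >= 1L, max_cycles >= 0L, max_added >= 0L)
  structure(list(top_screen = top_screen, tol = tol,
                 max_cycles = max_cycles, max_added = max_added, caps = caps,
                 alpha_grid = alpha_grid, nlambda = nlambda,
                 allow_self = allow_self, pair_filter = pair_filter,
                 heredity = heredity, metric = metric, seed = seed),
            class = "selection_config")
}

#' A (possibly partial) selection of features and interaction terms
#'
#' @param features character vector of selected feature names.
#' @param terms list of selected [interaction_term()]s.
#' @param trajectory data frame of accepted steps (`action`, `what`,
#'   `score`).
#' @param config configuration echo.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(features = character(), terms = list(),
                             trajectory = NULL, config = list()) {
  if (is.null(trajectory))
    trajectory <- data.frame(action = character(), what = character(),
                             score = numeric(), stringsAsFactors = FALSE)
  structure(list(features = features, terms = terms,
                 trajectory = trajectory, config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d features, %d interaction terms\n",
              length(x$features), length(x$terms)))
  if (length(x$terms) > 0L)
    cat("  terms:", paste(vapply(x$terms, term_key, character(1)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param result a `selection_result`.
#' @param path output path.
#' @param catalogue optional `variable_catalogue` used to group features by
#'   category in the file.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path, catalogue = NULL) {
  feats <- if (is.null(catalogue)) list(all = result$features) else {
    split(result$features,
          catalogue$category[match(result$features, catalogue$name)])
  }
  cfg <- result$config
  cfg$pair_filter <- NULL  # closures are not serializable
  jsonlite::write_json(
    list(features = feats, interactions = terms_to_list(result$terms),
         trajectory = result$trajectory, config = cfg),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## ---- fold evaluation context -----------------------------------------------
## Per fold: scaler fitted on training rows only (no validation leakage),
## normalized train/validation sub-panels, and a cache of interaction columns
## keyed by term, so repeated stepwise evaluations never rebuild Z.
new_fold_ctx <- function(panel, folds, registry, metric) {
  if (length(folds) == 0L) stop("fold scheme is empty")
  fcs <- lapply(folds, function(f) {
    if (length(f$train) == 0L)
      stop("fold ", f$label, " has no training rows")
    sc <- fit_scaler(panel, f$train)
    list(tr = apply_scaler(subset_panel(panel, f$train), sc),
         va = apply_scaler(subset_panel(panel, f$validation), sc),
         label = f$label, axis = f$axis,
         zcache = new.env(parent = emptyenv()))
  })
  list(folds = fcs, registry = registry, metric = metric)
}

fold_Z <- function(fc, side, terms, registry) {
  n <- n_samples(fc[[side]])
  if (length(terms) == 0L) return(matrix(0, n, 0L))
  cols <- lapply(terms, function(tm) {
    key <- paste0(side, "|", term_key(tm))
    z <- fc$zcache[[key]]
    if (is.null(z)) {
      z <- eval_kernel(registry, tm$kernel_id,
                       fc[[side]]$X[, tm$var_a], fc[[side]]$X[, tm$var_b])
      assign(key, z, envir = fc$zcache)
    }
    z
  })
  do.call(cbind, cols)
}

score_set <- function(ctx, features, terms) {
  vals <- vapply(ctx$folds, function(fc) {
    Dtr <- cbind(1, fc$tr$X[, features, drop = FALSE],
                 fold_Z(fc, "tr", terms, ctx$registry))
    if (nrow(Dtr) <= ncol(Dtr))
      stop("fold ", fc$label, ": ", nrow(Dtr),
           " training rows cannot identify ", ncol(Dtr), " coefficients")
    cf <- ols_coef(Dtr, fc$tr$y)
    Dva <- cbind(1, fc$va$X[, features, drop = FALSE],
                 fold_Z(fc, "va", terms, ctx$registry))
    unname(evaluate_metrics(fc$va$y, drop(Dva %*% cf), ctx$metric))
  }, numeric(1))
  names(vals) <- vapply(ctx$folds, `[[`, character(1), "label")
  vals
}

#' Spatio-temporal robustness score of a candidate model
#'
#' For every blocked fold the linear model with the given features and
#' interaction terms is fitted on the fold's training rows (normalization
#' included — the scaler is refitted inside each fold) and the error metric
#' is evaluated on the fold's validation rows. The aggregate robustness score
#' is the unweighted mean across folds, pooling temporal and spatial axes;
#' lower is better.
#'
#' @param features character vector of feature names.
#' @param terms list of [interaction_term()]s.
#' @param panel a `sample_panel` with yields, natural units.
#' @param folds a `fold_scheme`.
#' @param registry a `kernel_registry`.
#' @param metric `"RRMSE"`, `"RMSE"` or `"MAE"`.
#' @return An object of class `robustness_report` with `per_fold`,
#'   `aggregate`, `metric` and `axes`.
#' @export
robustness_score <- function(features, terms, panel, folds,
                             registry = default_kernel_registry(),
                             metric = "RRMSE") {
  ctx <- new_fold_ctx(panel, folds, registry, metric)
  vals <- score_set(ctx, features, terms)
  structure(list(per_fold = vals, aggregate = mean(vals), metric = metric,
                 axes = vapply(folds, `[[`, character(1), "axis")),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report (%s): aggregate %.4f over %d folds\n",
              x$metric, x$aggregate, length(x$per_fold)))
  invisible(x)
}

## ---- elastic-net pre-screen ------------------------------------------------

#' Elastic-net pre-screen of one variable category
#'
#' Shortlists high-quality features within a category before the stepwise
#' search. The (alpha, lambda) grid is scored on the blocked fold scheme (fit
#' on each fold's training rows, error on its validation rows; scalers
#' refitted per fold) and the grid point with the lowest mean validation RMSE
#' wins (ties prefer the sparser, larger-lambda point). Variables with
#' nonzero coefficients in the full-data refit at the winning grid point are
#' returned, strongest first, truncated to `cap`.
#'
#' @param panel a `sample_panel` with yields, natural units.
#' @param category `"weather"`, `"soil"` or `"management"`.
#' @param folds a `fold_scheme`.
#' @param alpha_grid elastic-net mixing parameters to search.
#' @param nlambda penalty path length per alpha.
#' @param cap maximum number of features returned.
#' @return Character vector of selected feature names (possibly empty).
#' @export
elastic_net_prescreen <- function(panel, category, folds,
                                  alpha_grid = c(0.1, 0.5, 0.9),
                                  nlambda = 50L, cap = Inf) {
  if (is.null(panel$y)) stop("panel has no observed yields")
  vars <- panel$catalogue$name[panel$catalogue$category == category]
  if (length(vars) == 0L) stop("category '", category, "' has no variables")
  if (stats::var(panel$y) == 0) return(character(0))
  if (length(vars) == 1L) return(utils::head(vars, cap))
  sc_all <- fit_scaler(panel)
  np <- apply_scaler(panel, sc_all)
  Xall <- np$X[, vars, drop = FALSE]
  ## common lambda path from the full data (cv.glmnet's convention)
  path <- glmnet::glmnet(Xall, panel$y, alpha = min(alpha_grid[alpha_grid > 0],
                                                    0.5),
                         nlambda = nlambda)
  lambdas <- path$lambda
  ctx <- new_fold_ctx(panel, folds, default_kernel_registry(), "RMSE")
  best <- NULL
  for (alpha in alpha_grid) {
    errs <- matrix(NA_real_, length(ctx$folds), length(lambdas))
    for (fi in seq_along(ctx$folds)) {
      fc <- ctx$folds[[fi]]
      fit <- glmnet::glmnet(fc$tr$X[, vars, drop = FALSE], fc$tr$y,
                            alpha = alpha, lambda = lambdas)
      pred <- stats::predict(fit, fc$va$X[, vars, drop = FALSE])
      ## glmnet may drop path points; align by lambda
      li <- match(signif(fit$lambda, 10), signif(lambdas, 10))
      for (ci in seq_along(fit$lambda))
        errs[fi, li[ci]] <- sqrt(mean((fc$va$y - pred[, ci])^2))
    }
    mean_err <- colMeans(errs)
    ok <- which(!is.na(mean_err))
    if (length(ok) == 0L) next
    bi <- ok[which.min(mean_err[ok])]  # which.min: first (largest-lambda) tie
    if (is.null(best) || mean_err[bi] < best$err)
      best <- list(alpha = alpha, lambda = lambdas[bi], err = mean_err[bi])
  }
  if (is.null(best)) return(character(0))
  refit <- glmnet::glmnet(Xall, panel$y, alpha = best$alpha,
                          lambda = lambdas)
  cf <- as.matrix(stats::coef(refit, s = best$lambda, exact = FALSE))[-1L, 1L]
  nz <- cf[cf != 0]
  if (length(nz) == 0L) return(character(0))
  sel <- names(sort(abs(nz), decreasing = TRUE))
  utils::head(sel, cap)
}

## ---- stepwise search -------------------------------------------------------

canonical_candidate_order <- function(candidates, catalogue, registry) {
  key <- vapply(candidates, function(cd) {
    if (is.character(cd)) {
      sprintf("0|%06d|%06d|%03d", match(cd, catalogue$name), 0L, 0L)
    } else {
      sprintf("1|%06d|%06d|%03d",
              match(cd$var_a, catalogue$name),
              match(cd$var_b, catalogue$name),
              match(cd$kernel_id, kernel_ids(registry)))
    }
  }, character(1))
  candidates[order(key)]
}

add_candidate <- function(result, cd, score) {
  what <- if (is.character(cd)) cd else term_key(cd)
  if (is.character(cd)) result$features <- c(result$features, cd)
  else result$terms <- c(result$terms, list(cd))
  result$trajectory <- rbind(result$trajectory,
                             data.frame(action = "add", what = what,
                                        score = score,
                                        stringsAsFactors = FALSE))
  result
}

## scores within `tie_eps` of the minimum count as tied; the canonically
## first candidate wins (kernels spanning the same column space — e.g. the
## product and saturating-product kernels once both main effects are in the
## model — produce numerically identical fits, and the tie must not be
## decided by floating-point jitter)
tie_eps <- function(s) 1e-7 * (1 + abs(s))

candidate_sets <- function(current, cd, heredity) {
  fts <- current$features; tms <- current$terms
  if (is.character(cd)) fts <- c(fts, cd)
  else {
    tms <- c(tms, list(cd))
    if (heredity) fts <- union(fts, c(cd$var_a, cd$var_b))
  }
  list(features = fts, terms = tms)
}

forward_stepwise_ctx <- function(ctx, candidates, current, tol, max_added,
                                 heredity = FALSE) {
  cur_score <- suppressWarnings(
    mean(score_set(ctx, current$features, current$terms)))
  added <- 0L
  ## drop candidates already selected
  have <- c(current$features,
            vapply(current$terms, term_key, character(1)))
  candidates <- Filter(function(cd) {
    k <- if (is.character(cd)) cd else term_key(cd)
    !k %in% have
  }, candidates)
  while (added < max_added && length(candidates) > 0L) {
    sets <- lapply(candidates, candidate_sets, current = current,
                   heredity = heredity)
    ## exact collinearity among candidates (e.g. kernels equivalent up to
    ## linear parts) is expected here; the min-norm fit handles it quietly
    scores <- vapply(sets, function(ss)
      suppressWarnings(mean(score_set(ctx, ss$features, ss$terms))),
      numeric(1))
    smin <- min(scores)
    best <- which(scores <= smin + tie_eps(smin))[1L]  # canonical tie-break
    if (cur_score - scores[best] < tol) break
    cd <- candidates[[best]]
    if (heredity && !is.character(cd)) {
      for (v in setdiff(c(cd$var_a, cd$var_b), current$features))
        current <- add_candidate(current, v, scores[best])
    }
    current <- add_candidate(current, cd, scores[best])
    cur_score <- scores[best]
    candidates <- candidates[-best]
    added <- added + 1L
  }
  current
}

#' Greedy forward stepwise selection scored by blocked validation folds
#'
#' Repeatedly adds the candidate (feature name or interaction term) whose
#' inclusion most improves the aggregate robustness score, while the
#' improvement is at least `tol` and fewer than `max_added` candidates have
#' been accepted. Ties break by canonical candidate order (catalogue index,
#' then kernel order); the procedure is fully deterministic.
#'
#' @param candidates list of feature names and/or [interaction_term()]s.
#' @param current a `selection_result` to extend.
#' @param panel a `sample_panel` with yields, natural units.
#' @param folds a `fold_scheme`.
#' @param registry a `kernel_registry`.
#' @param tol minimum aggregate-score improvement to accept an addition.
#' @param max_added maximum number of additions.
#' @param heredity evaluate and keep interaction terms together with their
#'   two main effects (strong heredity).
#' @param metric robustness metric.
#' @return The extended `selection_result` (unchanged input when nothing
#'   improves).
#' @export
forward_stepwise <- function(candidates, current, panel, folds,
                             registry = default_kernel_registry(),
                             tol = 0.05, max_added = Inf, heredity = FALSE,
                             metric = "RRMSE") {
  stopifnot(tol >= 0)
  ctx <- new_fold_ctx(panel, folds, registry, metric)
  candidates <- canonical_candidate_order(candidates, panel$catalogue,
                                          registry)
  forward_stepwise_ctx(ctx, candidates, current, tol, max_added, heredity)
}

backward_eliminate_ctx <- function(ctx, current, tol, terms_only = FALSE) {
  repeat {
    k_feat <- if (terms_only) character(0) else current$features
    n_items <- length(k_feat) + length(current$terms)
    if (n_items == 0L) break
    cur_score <- suppressWarnings(
      mean(score_set(ctx, current$features, current$terms)))
    scores <- numeric(n_items)
    for (ii in seq_len(n_items)) {
      fts <- current$features; tms <- current$terms
      if (ii <= length(k_feat)) fts <- fts[-ii]
      else tms <- tms[-(ii - length(k_feat))]
      scores[ii] <- suppressWarnings(mean(score_set(ctx, fts, tms)))
    }
    smin <- min(scores)
    best <- which(scores <= smin + tie_eps(smin))[1L]
    if (scores[best] - cur_score > tol) break  # every removal worsens > tol
    if (best <= length(k_feat)) {
      what <- current$features[best]
      current$features <- current$features[-best]
    } else {
      ti <- best - length(k_feat)
      what <- term_key(current$terms[[ti]])
      current$terms <- current$terms[-ti]
    }
    current$trajectory <- rbind(current$trajectory,
                                data.frame(action = "drop", what = what,
                                           score = scores[best],
                                           stringsAsFactors = FALSE))
  }
  current
}

#' Backward elimination scored by blocked validation folds
#'
#' Repeatedly removes the selected feature or interaction term whose removal
#' most improves the aggregate robustness score (or degrades it least, within
#' `tol`); stops when every possible removal would worsen the score by more
#' than `tol`. With `tol = Inf` everything is stripped down to the
#' intercept-only model.
#'
#' @inheritParams forward_stepwise
#' @param current a `selection_result` to prune.
#' @return The pruned `selection_result` (a subset of the input selection).
#' @export
backward_eliminate <- function(current, panel, folds,
                               registry = default_kernel_registry(),
                               tol = 0.05, metric = "RRMSE") {
  stopifnot(tol >= 0)
  ctx <- new_fold_ctx(panel, folds, registry, metric)
  backward_eliminate_ctx(ctx, current, tol)
}

## Residual-correlation screen: top `k` candidate terms by the absolute
## correlation of the candidate column with the current model's training
## residuals, after projecting {1, x_a, x_b} out of the candidate column.
## The projection matters: a raw product column is dominated by its linear
## part, which the model's main effects already absorb, so correlating the
## raw column would dilute exactly the interaction-specific signal the
## screen is after.
screen_candidates <- function(np, resid, catalogue, registry, k,
                              allow_self, pair_filter, exclude_keys) {
  en <- enumerate_candidates(catalogue, registry, allow_self = allow_self,
                             pair_filter = pair_filter)
  rc <- resid - mean(resid)
  rs <- sqrt(sum(rc^2))
  if (rs == 0) return(list())
  best_terms <- vector("list", k)
  best_scores <- rep(-Inf, k)
  worst <- 1L
  repeat {
    tm <- en$next_term()
    if (is.null(tm)) break
    if (term_key(tm) %in% exclude_keys) next
    z <- eval_kernel(registry, tm$kernel_id,
                     np$X[, tm$var_a], np$X[, tm$var_b])
    A <- cbind(1, np$X[, tm$var_a], np$X[, tm$var_b])
    cf <- tryCatch(solve(crossprod(A), crossprod(A, z)),
                   error = function(e) NULL)  # degenerate pair: skip proj
    zc <- if (is.null(cf)) z - mean(z) else z - drop(A %*% cf)
    zs <- sqrt(sum(zc^2))
    if (zs < 1e-10) next
    sc <- abs(sum(zc * rc)) / (zs * rs)
    if (sc > best_scores[worst]) {
      best_scores[worst] <- sc
      best_terms[[worst]] <- tm
      worst <- which.min(best_scores)
    }
  }
  keep <- is.finite(best_scores) & !vapply(best_terms, is.null, logical(1))
  best_terms[keep][order(best_scores[keep], decreasing = TRUE)]
}

#' Iterative search for spatio-temporally robust features and interactions
#'
#' The full selection pipeline: (0) per-category elastic-net pre-screen of
#' the additive features; then repeated cycles of (a) residual screening —
#' all candidate interaction terms are ranked by the absolute correlation of
#' their column with the current model's training residuals and the top
#' `top_screen` are shortlisted, (b) forward stepwise addition over the
#' shortlist, and (c) backward elimination of interaction terms — until a
#' full cycle changes nothing or `max_cycles` is reached. Every accepted step
#' must improve the aggregate blocked-validation score by at least `tol`.
#'
#' @param panel a `sample_panel` with yields, natural units.
#' @param folds a `fold_scheme` mixing temporal and spatial blocks.
#' @param registry a `kernel_registry`.
#' @param config a [selection_config()].
#' @return A `selection_result` with features, interaction terms and the
#'   accepted-step trajectory.
#' @export
search_robust_interactions <- function(panel, folds,
                                       registry = default_kernel_registry(),
                                       config = selection_config()) {
  feats <- character(0)
  for (cc in c("weather", "soil", "management")) {
    if (!any(panel$catalogue$category == cc)) next
    cap <- if (cc %in% names(config$caps)) config$caps[[cc]] else Inf
    feats <- c(feats,
               elastic_net_prescreen(panel, cc, folds,
                                     alpha_grid = config$alpha_grid,
                                     nlambda = config$nlambda, cap = cap))
  }
  result <- selection_result(features = feats,
                             config = c(unclass(config)[
                               setdiff(names(config), "pair_filter")]))
  if (config$max_cycles == 0L) return(result)
  ctx <- new_fold_ctx(panel, folds, registry, config$metric)
  sc_all <- fit_scaler(panel)
  np <- apply_scaler(panel, sc_all)
  for (cycle in seq_len(config$max_cycles)) {
    before_keys <- vapply(result$terms, term_key, character(1))
    ## residuals of the current model on the full training panel
    fit <- fit_model(panel, result$features, result$terms, registry,
                     scaler = sc_all)
    resid <- panel$y - predict(fit, panel)
    shortlist <- screen_candidates(np, resid, panel$catalogue, registry,
                                   config$top_screen, config$allow_self,
                                   config$pair_filter, before_keys)
    shortlist <- canonical_candidate_order(shortlist, panel$catalogue,
                                           registry)
    result <- forward_stepwise_ctx(ctx, shortlist, result, config$tol,
                                   config$max_added,
                                   heredity = isTRUE(config$heredity))
    result <- backward_eliminate_ctx(ctx, result, config$tol,
                                     terms_only = TRUE)
    after_keys <- vapply(result$terms, term_key, character(1))
    if (identical(sort(before_keys), sort(after_keys))) break
  }
  result
}
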