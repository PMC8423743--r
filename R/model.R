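#' Fit the interaction regression model by ordinary least squares
#'
#' The model is linear in the selected features and the kernel-encoded
#' interaction columns:
#' `y_i = b0 + sum_j beta_j X_ij + sum_m b_m Z_im + e_i`,
#' with `X` on the normalized `[0, 1]` scale and `Z` built from `X` through
#' the kernel registry.
#'
#' @param panel a `sample_panel` with observed yields. If the panel is in
#'   natural units a min-max scaler is fitted on `train_rows` (default: all
#'   rows) unless `scaler` is supplied; a pre-normalized panel is used as-is.
#' @param features character vector of selected additive feature names.
#' @param terms list of [interaction_term()]s.
#' @param registry a `kernel_registry`.
#' @param scaler optional pre-specified `scaler` (e.g. known bounds).
#' @param train_rows rows used to fit the scaler when none is given.
#' @param metadata free-form list stored with the model (e.g. training years,
#'   seed).
#' @return An object of class `yield_model`.
#' @export
fit_model <- function(panel, features = character(), terms = list(),
                      registry = default_kernel_registry(), scaler = NULL,
                      train_rows = NULL, metadata = list()) {
  if (is.null(panel$y)) stop("panel has no observed yields to fit on")
  np <- panel
  if (!panel$normalized) {
    if (is.null(scaler))
      scaler <- fit_scaler(panel, train_rows %||% seq_len(n_samples(panel)))
    np <- apply_scaler(panel, scaler)
  }
  miss <- setdiff(features, np$catalogue$name)
  if (length(miss) > 0L)
    stop("unknown feature(s): ", paste(miss, collapse = ", "))
  Z <- build_interaction_matrix(np, terms, registry)
  D <- cbind(`(Intercept)` = 1,
             np$X[, features, drop = FALSE], Z)
  if (n_samples(np) <= ncol(D))
    stop("n = ", n_samples(np), " samples cannot identify ", ncol(D),
         " coefficients")
  coefs <- ols_coef(D, np$y)
  structure(list(
    intercept = unname(coefs[1L]),
    beta = stats::setNames(coefs[seq_along(features) + 1L], features),
    b = stats::setNames(coefs[-seq_len(1L + length(features))],
                        vapply(terms, term_key, character(1))),
    terms = terms,
    scaler = scaler,
    catalogue = np$catalogue,
    registry = registry,
    metadata = metadata), class = "yield_model")
}

## least squares with a minimum-norm fallback for rank-deficient designs
ols_coef <- function(D, y) {
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("design is rank deficient (rank ", qrD$rank, " < ", ncol(D),
            " columns); using the minimum-norm least-squares solution — ",
            "consider fewer or less collinear terms")
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    coefs <- drop(coefs)
  } else {
    coefs <- qr.coef(qrD, y)
  }
  stats::setNames(coefs, colnames(D))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.yield_model <- function(x, ...) {
  cat(sprintf(
    "yield_model: intercept %.4f, %d additive features, %d interaction terms\n",
    x$intercept, length(x$beta), length(x$b)))
  invisible(x)
}

## normalize a natural-units panel with the model scaler; verify the schema
model_panel <- function(object, panel) {
  if (!identical(panel$catalogue$name, object$catalogue$name))
    stop("panel variables do not match the model's catalogue; refusing to ",
         "predict on a mismatched schema")
  if (panel$normalized) panel else {
    if (is.null(object$scaler))
      stop("model has no scaler; supply a normalized panel")
    apply_scaler(panel, object$scaler)
  }
}

#' Predict yields with a fitted interaction regression model
#'
#' @param object a `yield_model`.
#' @param panel a `sample_panel` with the same variable catalogue the model
#'   was trained on (natural units — the model's scaler is applied — or
#'   already normalized).
#' @param ... unused.
#' @return Numeric vector of predicted yields (t/ha).
#' @export
predict.yield_model <- function(object, panel, ...) {
  np <- model_panel(object, panel)
  Z <- build_interaction_matrix(np, object$terms, object$registry)
  pred <- rep(object$intercept, n_samples(np))
  if (length(object$beta) > 0L)
    pred <- pred + drop(np$X[, names(object$beta), drop = FALSE] %*%
                          object$beta)
  if (length(object$b) > 0L)
    pred <- pred + drop(Z %*% object$b)
  pred
}

#' Prediction-error metrics
#'
#' Computes any of
#' `RMSE = sqrt(mean(e^2))`,
#' `RRMSE = 100 * RMSE / mean(observed)` (percent of mean observed yield),
#' `RSE = sum(e^2) / sum((y - mean(y))^2)`,
#' `MAE = mean(|e|)`,
#' `RAE = sum(|e|) / sum(|y - mean(y)|)`,
#' `R2 = 1 - RSE`.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @param metrics subset of `c("RMSE","RRMSE","RSE","MAE","RAE","R2")`.
#' @return Named numeric vector of the requested metrics.
#' @export
evaluate_metrics <- function(observed, predicted,
                             metrics = c("RMSE", "RRMSE", "RSE", "MAE",
                                         "RAE", "R2")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (length(observed) != length(predicted) || length(observed) == 0L)
    stop("observed and predicted must be nonempty and of equal length")
  e <- observed - predicted
  ybar <- mean(observed)
  out <- numeric(0)
  needs_var <- any(c("RSE", "RAE", "R2") %in% metrics)
  ss <- sum((observed - ybar)^2)
  sa <- sum(abs(observed - ybar))
  if (needs_var && (ss == 0 || sa == 0))
    stop("observed values have zero variance; RSE/RAE/R2 undefined")
  for (m in metrics) {
    out[m] <- switch(m,
      RMSE = sqrt(mean(e^2)),
      RRMSE = {
        if (ybar == 0) stop("RRMSE undefined: mean(observed) is 0")
        100 * sqrt(mean(e^2)) / ybar
      },
      RSE = sum(e^2) / ss,
      MAE = mean(abs(e)),
      RAE = sum(abs(e)) / sa,
      R2 = 1 - sum(e^2) / ss)
  }
  out
}

#' Dissect predicted yield into category contributions
#'
#' Each prediction is split into the additive contribution of the weather,
#' soil, and management features, the summed kernel-interaction contribution,
#' and the intercept; per sample these five parts add up exactly to the
#' prediction.
#'
#' @param model a `yield_model`.
#' @param panel a compatible `sample_panel`.
#' @return A data frame of class `contribution_breakdown` with columns
#'   `county_id, year, intercept, weather, soil, management, interaction,
#'   total`.
#' @export
decompose_contributions <- function(model, panel) {
  np <- model_panel(model, panel)
  n <- n_samples(np)
  parts <- matrix(0, n, 4,
                  dimnames = list(NULL, c("weather", "soil", "management",
                                          "interaction")))
  if (length(model$beta) > 0L) {
    cats <- np$catalogue$category[match(names(model$beta),
                                        np$catalogue$name)]
    for (cc in c("weather", "soil", "management")) {
      sel <- names(model$beta)[cats == cc]
      if (length(sel) > 0L)
        parts[, cc] <- drop(np$X[, sel, drop = FALSE] %*% model$beta[sel])
    }
  }
  if (length(model$b) > 0L) {
    Z <- build_interaction_matrix(np, model$terms, model$registry)
    parts[, "interaction"] <- drop(Z %*% model$b)
  }
  out <- data.frame(county_id = np$rows$county_id, year = np$rows$year,
                    intercept = rep(model$intercept, n),
                    weather = parts[, "weather"], soil = parts[, "soil"],
                    management = parts[, "management"],
                    interaction = parts[, "interaction"],
                    stringsAsFactors = FALSE)
  out$total <- out$intercept + out$weather + out$soil + out$management +
    out$interaction
  class(out) <- c("contribution_breakdown", "data.frame")
  out
}

#' Partial dependence of predicted yield on one or two variables
#'
#' For each grid point the variable(s) are clamped to the point across all
#' panel rows (on the normalized scale) and predictions are averaged over
#' rows — the marginal effect of the variable(s) on predicted yield.
#'
#' @param model a `yield_model`.
#' @param panel a compatible `sample_panel` providing the averaging
#'   population.
#' @param vars one or two catalogue variable names.
#' @param grid numeric vector of normalized grid points in `[0, 1]` (one
#'   variable), or a list of two such vectors.
#' @return A data frame: grid coordinates (normalized, plus original units
#'   via the model scaler when available) and the partial-dependence value
#'   `pd` (t/ha).
#' @export
partial_dependence <- function(model, panel, vars,
                               grid = seq(0, 1, length.out = 21)) {
  if (!length(vars) %in% 1:2) stop("vars must name one or two variables")
  miss <- setdiff(vars, model$catalogue$name)
  if (length(miss) > 0L)
    stop("unknown variable(s): ", paste(miss, collapse = ", "))
  np <- model_panel(model, panel)
  if (!is.list(grid)) grid <- rep(list(grid), length(vars))
  if (any(lengths(grid) == 0L)) stop("empty grid")
  pts <- if (length(vars) == 1L) {
    data.frame(g1 = grid[[1L]])
  } else {
    expand.grid(g1 = grid[[1L]], g2 = grid[[2L]])
  }
  pd <- numeric(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    Xc <- np$X
    Xc[, vars[1L]] <- pts$g1[r]
    if (length(vars) == 2L) Xc[, vars[2L]] <- pts$g2[r]
    clamped <- new_panel(np$rows, Xc, np$y, np$catalogue, normalized = TRUE)
    pd[r] <- mean(predict(model, clamped))
  }
  out <- data.frame(variable_1 = vars[1L], value_1 = pts$g1)
  if (!is.null(model$scaler))
    out$value_1_original <- invert_scaler(pts$g1, model$scaler, vars[1L])
  if (length(vars) == 2L) {
    out$variable_2 <- vars[2L]
    out$value_2 <- pts$g2
    if (!is.null(model$scaler))
      out$value_2_original <- invert_scaler(pts$g2, model$scaler, vars[2L])
  }
  out$pd <- pd
  out
}

#' Serialize a fitted model to JSON
#'
#' The file embeds the coefficients, interaction terms, scaler, and the full
#' variable catalogue, so [read_model()] can refuse panels with a mismatched
#' schema. Kernels are stored by id; reading reattaches them from the
#' supplied registry.
#'
#' @param model a `yield_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    intercept = model$intercept,
    beta = as.list(model$beta),
    interactions = lapply(seq_along(model$terms), function(m)
      c(terms_to_list(model$terms[m])[[1L]],
        list(coefficient = unname(model$b[m])))),
    scaler = if (is.null(model$scaler)) NULL else
      list(min = as.list(stats::setNames(model$scaler$min,
                                         model$scaler$names)),
           max = as.list(stats::setNames(model$scaler$max,
                                         model$scaler$names))),
    catalogue = model$catalogue[, c("name", "category", "week", "depth")],
    metadata = model$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model
#' @param path JSON path written by [write_model()].
#' @param registry kernel registry providing the kernel functions named in
#'   the file.
#' @return A `yield_model`.
#' @export
read_model <- function(path, registry = default_kernel_registry()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  cat <- obj$catalogue
  cat$week <- as.integer(cat$week)
  cat$depth <- as.character(cat$depth)
  catalogue <- validate_catalogue(
    structure(cat, class = c("variable_catalogue", "data.frame")))
  ints <- obj$interactions
  terms <- list(); b <- numeric(0)
  if (length(ints) > 0L && NROW(ints) > 0L) {
    ints <- as.data.frame(ints)
    terms <- lapply(seq_len(nrow(ints)), function(m)
      interaction_term(ints$var_a[m], ints$var_b[m], ints$kernel_id[m]))
    b <- stats::setNames(as.numeric(ints$coefficient),
                         vapply(terms, term_key, character(1)))
  }
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    mn <- unlist(obj$scaler$min); mx <- unlist(obj$scaler$max)
    scaler <- new_scaler(mn, mx[names(mn)])
  }
  structure(list(intercept = as.numeric(obj$intercept),
                 beta = stats::setNames(as.numeric(unlist(obj$beta)),
                                        names(obj$beta)),
                 b = b, terms = terms, scaler = scaler,
                 catalogue = catalogue, registry = registry,
                 metadata = as.list(obj$metadata)), class = "yield_model")
}
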