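## run code under a seed, restoring the caller's RNG state afterwards
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic county-year panel generator
#'
#' The generator emulates the statistical structure the interaction
#' regression assumes: weekly weather series (AR(1) fluctuations around a
#' seasonal sinusoid, shared county offsets), static per-county soil
#' profiles, logistic management progress curves, and yields composed of
#' planted additive effects, planted kernel interactions, a per-county
#' linear technology trend, and Gaussian noise. All effect coefficients act
#' on the generator's own normalized `[0, 1]` scale, whose per-column bounds
#' are recorded in the ground truth so noiseless yields are exactly
#' recomputable.
#'
#' @param n_counties number of counties.
#' @param years integer vector of panel years.
#' @param weather_weeks calendar weeks carrying weekly weather columns.
#' @param progress_weeks calendar weeks carrying planting-progress columns.
#' @param beta0 intercept (t/ha).
#' @param beta named numeric vector of true additive effects (t/ha per unit
#'   of normalized feature); names must be generated columns.
#' @param interactions list of `list(var_a, var_b, kernel_id, b)` planted
#'   kernel interactions (coefficients in t/ha).
#' @param noise_sd yield noise standard deviation sigma (t/ha).
#' @param progress_noise_sd survey/reporting noise SD on the weekly
#'   planting-progress fractions.
#' @param trend_mean,trend_sd mean and spread of the per-county yield trend
#'   slope (t/ha per year); `trend_sd = 0` with `trend_mean = 0` disables
#'   the trend block (no `M_yield_trend` column).
#' @param seed integer seed fixing the whole generation stream.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_counties = 50L, years = 1998:2017,
                         weather_weeks = 20:29, progress_weeks = 20:23,
                         beta0 = 6,
                         beta = c(W_tmax_wk24 = -1.2, W_prcp_wk22 = 0.9,
                                  S_om_d0_5 = 1.1, M_planted_wk21 = -0.5,
                                  W_srad_wk26 = 0.6),
                         interactions = list(
                           list(var_a = "W_prcp_wk23", var_b = "W_tmax_wk25",
                                kernel_id = "product", b = 2.0),
                           list(var_a = "W_tmin_wk21",
                                var_b = "M_planted_wk22",
                                kernel_id = "product", b = -1.6)),
                         noise_sd = 0.3, progress_noise_sd = 0.08,
                         trend_mean = 0, trend_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0, progress_noise_sd >= 0, trend_sd >= 0,
            n_counties >= 1L,
            length(years) >= 1L,
            all(weather_weeks >= 13L & weather_weeks <= 52L))
  structure(list(n_counties = as.integer(n_counties),
                 years = as.integer(years),
                 weather_weeks = as.integer(weather_weeks),
                 progress_weeks = as.integer(progress_weeks),
                 beta0 = beta0, beta = beta, interactions = interactions,
                 noise_sd = noise_sd, progress_noise_sd = progress_noise_sd,
                 trend_mean = trend_mean,
                 trend_sd = trend_sd, seed = as.integer(seed)),
            class = "synth_config")
}

## weekly weather process parameters by type (natural units)
weather_process <- function() {
  list(tmax = list(mean = 22, amp = 8, ar = 0.5, sd = 2.5, county_sd = 1.0),
       tmin = list(mean = 10, amp = 8, ar = 0.5, sd = 2.5, county_sd = 1.0),
       prcp = list(mean = 20, amp = 5, ar = 0.3, sd = 8.0, county_sd = 3.0),
       srad = list(mean = 18, amp = 6, ar = 0.4, sd = 3.0, county_sd = 1.0))
}

## soil variable parameters: value = depth-attenuated county draw
soil_process <- function() {
  list(om = list(mean = 3, sd = 0.8),
       clay = list(mean = 25, sd = 6))
}

soil_depths <- function() c("0_5", "5_10", "10_15", "15_30", "30_45")

seasonal_mean <- function(pp, week) {
  pp$mean + pp$amp * sin(2 * pi * (week - 13) / 40)
}

#' Generate a synthetic county-year panel with ground truth
#'
#' See [synth_config()] for the generating process. Weather draws are
#' clamped to their per-column truth bounds (mean +/- 2.5 total SD), so the
#' normalized design lies strictly inside `[0, 1]` and the ground-truth
#' scaler reproduces generation exactly.
#'
#' @param config a `synth_config`.
#' @return A list with `panel` (a `sample_panel`, natural units, yields
#'   observed) and `truth` (class `synthetic_truth`: true coefficients,
#'   interactions, noise SD, per-county trend slopes, and the generator's
#'   scaler).
#' @export
generate_panel <- function(config) {
  with_seed_(config$seed, generate_panel_(config))
}

generate_panel_ <- function(cfg) {
  counties <- sprintf("c%03d", seq_len(cfg$n_counties))
  rows <- expand.grid(year = cfg$years, county_id = counties,
                      stringsAsFactors = FALSE)[, c("county_id", "year")]
  n <- nrow(rows)
  crow <- match(rows$county_id, counties)
  cols <- list(); lo <- numeric(0); hi <- numeric(0)
  cat_rows <- list()
  add_col <- function(name, values, category, week, depth, lo_v, hi_v) {
    cols[[name]] <<- values
    lo[name] <<- lo_v; hi[name] <<- hi_v
    cat_rows[[name]] <<- data.frame(name = name, category = category,
                                    week = week, depth = depth,
                                    stringsAsFactors = FALSE)
  }
  ## weather: AR(1) around a seasonal sinusoid plus a county offset
  for (ty in names(weather_process())) {
    pp <- weather_process()[[ty]]
    sd_inf <- pp$sd / sqrt(1 - pp$ar^2)
    sd_tot <- sqrt(pp$county_sd^2 + sd_inf^2)
    ceff <- stats::rnorm(cfg$n_counties, 0, pp$county_sd)[crow]
    W <- length(cfg$weather_weeks)
    E <- matrix(0, n, W)
    E[, 1L] <- stats::rnorm(n, 0, sd_inf)
    if (W > 1L) for (w in 2:W)
      E[, w] <- pp$ar * E[, w - 1L] + stats::rnorm(n, 0, pp$sd)
    for (wi in seq_len(W)) {
      wk <- cfg$weather_weeks[wi]
      mu <- seasonal_mean(pp, wk)
      v <- mu + ceff + E[, wi]
      lo_v <- mu - 2.5 * sd_tot; hi_v <- mu + 2.5 * sd_tot
      add_col(sprintf("W_%s_wk%d", ty, wk), pmin(hi_v, pmax(lo_v, v)),
              "weather", as.integer(wk), NA_character_, lo_v, hi_v)
    }
  }
  ## soil: static per county; a shared profile attenuated with depth plus an
  ## independent per-depth county perturbation (so depths are correlated but
  ## never collinear)
  for (sv in names(soil_process())) {
    pp <- soil_process()[[sv]]
    base <- stats::rnorm(cfg$n_counties, pp$mean, pp$sd)
    for (di in seq_along(soil_depths())) {
      att <- 1 - 0.08 * (di - 1)
      mu <- pp$mean * att
      sd_col <- pp$sd * sqrt(att^2 + 0.35^2)
      lo_v <- mu - 2.5 * sd_col; hi_v <- mu + 2.5 * sd_col
      v <- (base * att + stats::rnorm(cfg$n_counties, 0, 0.35 * pp$sd))[crow]
      add_col(sprintf("S_%s_d%s", sv, soil_depths()[di]),
              pmin(hi_v, pmax(lo_v, v)), "soil", NA_integer_,
              soil_depths()[di], lo_v, hi_v)
    }
  }
  ## management: logistic planting progress + planted acreage. Weekly
  ## progress reports carry independent survey/reporting noise on top of the
  ## county-year planting curve (without it, every weekly column would be a
  ## deterministic transform of the same latent planting date and the
  ## individual columns would not be identifiable).
  mid <- 21 + stats::rnorm(n, 0, 2)
  for (wk in cfg$progress_weeks)
    add_col(sprintf("M_planted_wk%d", wk),
            pmin(1, pmax(0, stats::plogis((wk - mid) / 1.5) +
                              stats::rnorm(n, 0, cfg$progress_noise_sd))),
            "management", as.integer(wk), NA_character_, 0, 1)
  lacres <- stats::rnorm(cfg$n_counties, 10, 0.3)[crow] +
    stats::rnorm(n, 0, 0.1)
  lac_sd <- sqrt(0.3^2 + 0.1^2)
  lac_lo <- 10 - 2.5 * lac_sd; lac_hi <- 10 + 2.5 * lac_sd
  lacres <- pmin(lac_hi, pmax(lac_lo, lacres))
  add_col("M_acres", exp(lacres), "management", NA_integer_, NA_character_,
          exp(lac_lo), exp(lac_hi))
  ## per-county technology trend
  has_trend <- cfg$trend_mean != 0 || cfg$trend_sd > 0
  y_mid <- stats::median(cfg$years)
  slopes <- rep(cfg$trend_mean, cfg$n_counties)
  if (cfg$trend_sd > 0) {
    slopes <- slopes + stats::rnorm(cfg$n_counties, 0, cfg$trend_sd)
    slopes <- pmin(cfg$trend_mean + 3 * cfg$trend_sd,
                   pmax(cfg$trend_mean - 3 * cfg$trend_sd, slopes))
  }
  trend_val <- slopes[crow] * (rows$year - y_mid)
  if (has_trend) {
    span <- max(abs(range(cfg$years - y_mid)))
    smax <- max(abs(cfg$trend_mean) + 3 * cfg$trend_sd, 1e-8)
    add_col("M_yield_trend", trend_val, "management", NA_integer_,
            NA_character_, -span * smax, span * smax)
  }
  X <- do.call(cbind, cols)
  catalogue <- do.call(rbind, cat_rows)
  class(catalogue) <- c("variable_catalogue", "data.frame")
  catalogue <- validate_catalogue(catalogue)
  scaler <- new_scaler(lo[colnames(X)], hi[colnames(X)])
  ## truth yields on the generator's normalized scale
  miss <- setdiff(c(names(cfg$beta),
                    unlist(lapply(cfg$interactions,
                                  function(it) c(it$var_a, it$var_b)))),
                  colnames(X))
  if (length(miss) > 0L)
    stop("true effect references non-generated variable(s): ",
         paste(miss, collapse = ", "))
  truth <- structure(list(beta0 = cfg$beta0, beta = cfg$beta,
                          interactions = cfg$interactions,
                          noise_sd = cfg$noise_sd,
                          trend = list(slopes = stats::setNames(slopes,
                                                                counties),
                                       year_mid = y_mid,
                                       enabled = has_trend),
                          scaler = scaler, seed = cfg$seed),
                     class = "synthetic_truth")
  pan0 <- new_panel(rows, X, NULL, catalogue, normalized = FALSE)
  y <- truth_yield(truth, pan0) + stats::rnorm(n, 0, cfg$noise_sd)
  list(panel = validate_panel(new_panel(rows, X, y, catalogue, FALSE)),
       truth = truth)
}

#' Noiseless ground-truth yields for a panel
#'
#' Recomputes `beta0 + sum beta_j Xn_ij + sum b_m K_m(Xn) + trend_c(year)`
#' from the ground truth alone (using the truth's own scaler), independent
#' of any fitted model.
#'
#' @param truth a `synthetic_truth`.
#' @param panel a `sample_panel` in natural units with the generated schema.
#' @param registry kernel registry resolving the planted kernel ids.
#' @return Numeric vector of noiseless yields (t/ha).
#' @export
truth_yield <- function(truth, panel,
                        registry = default_kernel_registry()) {
  np <- apply_scaler(panel, truth$scaler)
  y <- rep(truth$beta0, n_samples(np))
  if (length(truth$beta) > 0L)
    y <- y + drop(np$X[, names(truth$beta), drop = FALSE] %*% truth$beta)
  for (it in truth$interactions)
    y <- y + it$b * eval_kernel(registry, it$kernel_id,
                                np$X[, it$var_a], np$X[, it$var_b])
  if (isTRUE(truth$trend$enabled))
    y <- y + truth$trend$slopes[panel$rows$county_id] *
      (panel$rows$year - truth$trend$year_mid)
  unname(y)
}

#' Write ground truth to JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(beta0 = truth$beta0, beta = as.list(truth$beta),
         interactions = truth$interactions, noise_sd = truth$noise_sd,
         trend = list(slopes = as.list(truth$trend$slopes),
                      year_mid = truth$trend$year_mid,
                      enabled = truth$trend$enabled),
         scaler = list(min = as.list(stats::setNames(truth$scaler$min,
                                                     truth$scaler$names)),
                       max = as.list(stats::setNames(truth$scaler$max,
                                                     truth$scaler$names))),
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read ground truth from JSON
#' @param path path written by [write_truth()].
#' @return A `synthetic_truth`.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mn <- unlist(obj$scaler$min); mx <- unlist(obj$scaler$max)
  structure(list(beta0 = obj$beta0,
                 beta = unlist(obj$beta),
                 interactions = obj$interactions,
                 noise_sd = obj$noise_sd,
                 trend = list(slopes = unlist(obj$trend$slopes),
                              year_mid = obj$trend$year_mid,
                              enabled = isTRUE(obj$trend$enabled)),
                 scaler = new_scaler(mn, mx[names(mn)]),
                 seed = obj$seed), class = "synthetic_truth")
}

## canonical key for recovery matching: unordered pair for symmetric kernels
recovery_key <- function(var_a, var_b, kernel_id,
                         registry = default_kernel_registry()) {
  k <- registry[[kernel_id]]
  if (!is.null(k) && isTRUE(k$symmetric)) {
    vs <- sort(c(var_a, var_b))
    paste(vs[1L], vs[2L], kernel_id, sep = ":")
  } else paste(var_a, var_b, kernel_id, sep = ":")
}

#' Score a selection result against planted ground truth
#'
#' An interaction counts as recovered when both variables and the kernel
#' match (pair order ignored for symmetric kernels).
#'
#' @param truth a `synthetic_truth`.
#' @param result a `selection_result`.
#' @param model optional fitted `yield_model` whose interaction coefficients
#'   are compared with the planted ones (RMSE over matched terms).
#' @param registry kernel registry (for symmetry information).
#' @return A list: `recall`, `fdr` (both 0 when their denominator is 0),
#'   `n_true`, `n_selected`, `n_matched`, and `coef_rmse` (`NA` without a
#'   model or matches).
#' @export
score_recovery <- function(truth, result, model = NULL,
                           registry = default_kernel_registry()) {
  tk <- vapply(truth$interactions, function(it)
    recovery_key(it$var_a, it$var_b, it$kernel_id, registry), character(1))
  sk <- vapply(result$terms, function(tm)
    recovery_key(tm$var_a, tm$var_b, tm$kernel_id, registry), character(1))
  n_true <- length(tk); n_sel <- length(sk)
  n_matched <- sum(sk %in% tk)
  recall <- if (n_true == 0L) 0 else n_matched / n_true
  fdr <- if (n_sel == 0L) 0 else sum(!sk %in% tk) / n_sel
  coef_rmse <- NA_real_
  if (!is.null(model) && n_matched > 0L) {
    errs <- numeric(0)
    for (it in truth$interactions) {
      key <- recovery_key(it$var_a, it$var_b, it$kernel_id, registry)
      mi <- which(vapply(model$terms, function(tm)
        recovery_key(tm$var_a, tm$var_b, tm$kernel_id, registry),
        character(1)) == key)
      if (length(mi) == 1L) errs <- c(errs, model$b[mi] - it$b)
    }
    if (length(errs) > 0L) coef_rmse <- sqrt(mean(errs^2))
  }
  list(recall = recall, fdr = fdr, n_true = n_true, n_selected = n_sel,
       n_matched = n_matched, coef_rmse = coef_rmse)
}

#' The reference benchmark scenario
#'
#' Loads the fixture configuration shipped with the package: 50 counties by
#' 20 years (1000 rows), 40 weekly weather + 10 soil + 5 management
#' variables, two planted product interactions with `|b| / sigma >= 3`
#' (b = 2.0 and -1.6, sigma = 0.3 t/ha).
#'
#' @param seed generation seed.
#' @return A `synth_config`.
#' @export
reference_synth_config <- function(seed = 1L) {
  path <- system.file("extdata", "reference_scenario.json",
                      package = "interactreg", mustWork = TRUE)
  cfg <- synth_config_from_json(path)
  cfg$seed <- as.integer(seed)
  cfg
}

#' Read a generator configuration from JSON
#' @param path JSON file with `synth_config()` fields.
#' @return A `synth_config`.
#' @export
synth_config_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  synth_config(n_counties = obj$n_counties,
               years = unlist(obj$years),
               weather_weeks = unlist(obj$weather_weeks),
               progress_weeks = unlist(obj$progress_weeks),
               beta0 = obj$beta0, beta = unlist(obj$beta),
               interactions = obj$interactions,
               noise_sd = obj$noise_sd,
               progress_noise_sd = obj$progress_noise_sd %||% 0.08,
               trend_mean = obj$trend_mean %||% 0,
               trend_sd = obj$trend_sd %||% 0,
               seed = obj$seed %||% 1L)
}
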