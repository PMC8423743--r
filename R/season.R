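#' Build an in-season scenario ensemble for one county-year
#'
#' At forecast week `w`, weather and management are observed only through
#' week `w`. For the still-unobserved weeks, each historical donor year of
#' the county supplies one completion scenario: weekly columns with week
#' `<= w` (and all static columns — soil, non-weekly management) come from
#' the target row, weekly columns with week `> w` from the donor year.
#' Cumulative management-progress columns can either be copied raw from the
#' donor (`progress_splice = "copy"`) or rescaled so the donor's remaining
#' curve continues monotonically from the last observed progress value
#' (`"rescale"`, the default).
#'
#' @param target a one-row `sample_panel` (natural units) for the target
#'   county-year; weekly columns beyond `as_of_week` may hold placeholder
#'   values — they are never used.
#' @param history a `sample_panel` of fully observed past rows for the same
#'   county (the donor pool).
#' @param as_of_week integer in `[13, 52]`: last week with observations.
#' @param progress_splice `"rescale"` or `"copy"`.
#' @return An object of class `scenario_ensemble`: `as_of_week`, target
#'   `county_id`/`year`, `donor_years`, and `panel` (one completed row per
#'   donor year; the row's `year` labels the donor).
#' @export
build_scenarios <- function(target, history, as_of_week,
                            progress_splice = c("rescale", "copy")) {
  progress_splice <- match.arg(progress_splice)
  if (n_samples(target) != 1L) stop("target must be a single panel row")
  if (n_samples(history) == 0L) stop("empty history: no donor years")
  if (!identical(target$catalogue$name, history$catalogue$name))
    stop("target and history have different catalogues")
  if (as_of_week < 13L || as_of_week > 52L)
    stop("as_of_week must lie in [13, 52]")
  cat <- target$catalogue
  weekly <- !is.na(cat$week)
  future <- weekly & cat$week > as_of_week
  n_d <- n_samples(history)
  X <- matrix(rep(target$X[1L, ], each = n_d), nrow = n_d,
              dimnames = list(NULL, cat$name))
  X[, future] <- history$X[, future, drop = FALSE]
  if (progress_splice == "rescale") {
    ## management progress columns, grouped by their base name
    prog <- which(future & cat$category == "management")
    if (length(prog) > 0L) {
      base <- sub("_wk[0-9]+$", "", cat$name[prog])
      for (bs in unique(base)) {
        grp_all <- which(cat$category == "management" & !is.na(cat$week) &
                           sub("_wk[0-9]+$", "", cat$name) == bs)
        obs_idx <- grp_all[cat$week[grp_all] <= as_of_week]
        if (length(obs_idx) == 0L) next  # nothing observed: keep raw copy
        last <- obs_idx[which.max(cat$week[obs_idx])]
        obs_last <- target$X[1L, last]
        don_at_w <- history$X[, last]
        fut_idx <- grp_all[cat$week[grp_all] > as_of_week]
        for (ci in fut_idx) {
          scale <- ifelse(don_at_w < 1, (1 - obs_last) / (1 - don_at_w), 0)
          v <- obs_last + scale * (history$X[, ci] - don_at_w)
          X[, ci] <- pmin(1, pmax(obs_last, v))
        }
      }
    }
  }
  pan <- new_panel(data.frame(county_id = rep(target$rows$county_id[1L], n_d),
                              year = history$rows$year,
                              stringsAsFactors = FALSE),
                   X, NULL, cat, normalized = FALSE)
  structure(list(as_of_week = as.integer(as_of_week),
                 county_id = target$rows$county_id[1L],
                 year = target$rows$year[1L],
                 donor_years = history$rows$year,
                 panel = validate_panel(pan)),
            class = "scenario_ensemble")
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat(sprintf(
    "scenario_ensemble: %s/%d as of week %d, %d donor scenarios\n",
    x$county_id, x$year, x$as_of_week, length(x$donor_years)))
  invisible(x)
}

#' Weekly forecast from scenario ensembles
#'
#' Predicts every scenario of every weekly ensemble with the fitted model;
#' the week's forecast is the median across scenario predictions, with the
#' first and third quartiles as the uncertainty band (quartiles use linear
#' interpolation between order statistics, `stats::quantile` type 7).
#'
#' @param model a `yield_model`.
#' @param ensembles list of [build_scenarios()] ensembles, one per week.
#' @return A data frame of class `weekly_forecast`: `week, median, q1, q3,
#'   n_scenarios`, ordered by week.
#' @export
weekly_forecast <- function(model, ensembles) {
  if (inherits(ensembles, "scenario_ensemble")) ensembles <- list(ensembles)
  rows <- lapply(ensembles, function(ens) {
    preds <- predict(model, ens$panel)
    q <- stats::quantile(preds, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(week = ens$as_of_week, median = q[2L], q1 = q[1L], q3 = q[3L],
               n_scenarios = length(preds))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$week), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("weekly_forecast", "data.frame")
  out
}

#' Full-season forecast trajectory for one county-year
#'
#' Convenience wrapper: builds one scenario ensemble per week and forecasts
#' each with [weekly_forecast()]. The model is fitted once, pre-season, and
#' reused at every week.
#'
#' @param model a `yield_model`.
#' @param target a one-row `sample_panel` for the target county-year (fully
#'   observed; earlier weeks are treated as known at each forecast week).
#' @param history donor-pool `sample_panel` for the county.
#' @param weeks forecast weeks (default all weekly catalogue weeks).
#' @param progress_splice see [build_scenarios()].
#' @return A `weekly_forecast` data frame.
#' @export
season_forecast <- function(model, target, history, weeks = NULL,
                            progress_splice = c("rescale", "copy")) {
  progress_splice <- match.arg(progress_splice)
  if (is.null(weeks)) {
    wk <- target$catalogue$week
    weeks <- sort(unique(wk[!is.na(wk)]))
  }
  ens <- lapply(weeks, function(w)
    build_scenarios(target, history, w, progress_splice))
  weekly_forecast(model, ens)
}

#' Export a weekly forecast as CSV
#' @param forecast a `weekly_forecast`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_forecast <- function(forecast, path) {
  utils::write.csv(as.data.frame(forecast), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
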