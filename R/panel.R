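#' Variable catalogue for a county-year panel
#'
#' The catalogue records, for every explanatory column of a panel, its name,
#' its category (weather, soil, or management), and — where applicable — the
#' calendar week it refers to (weeks 13 to 52) or the soil depth layer label.
#'
#' @param name character vector of unique variable names.
#' @param category character vector, each one of `"weather"`, `"soil"`,
#'   `"management"`.
#' @param week integer vector of calendar weeks in `[13, 52]`, `NA` for
#'   non-weekly variables.
#' @param depth character vector of soil depth labels, `NA` where not
#'   applicable.
#' @return An object of class `variable_catalogue` (a data frame).
#' @export
variable_catalogue <- function(name, category,
                               week = rep(NA_integer_, length(name)),
                               depth = rep(NA_character_, length(name))) {
  cat <- data.frame(name = as.character(name),
                    category = as.character(category),
                    week = as.integer(week),
                    depth = as.character(depth),
                    stringsAsFactors = FALSE)
  class(cat) <- c("variable_catalogue", "data.frame")
  validate_catalogue(cat)
}

validate_catalogue <- function(cat) {
  if (anyDuplicated(cat$name))
    stop("duplicate variable name(s): ",
         paste(unique(cat$name[duplicated(cat$name)]), collapse = ", "))
  bad <- !cat$category %in% c("weather", "soil", "management")
  if (any(bad))
    stop("unknown category for variable(s): ",
         paste(cat$name[bad], collapse = ", "))
  wk <- cat$week[!is.na(cat$week)]
  if (any(wk < 13L | wk > 52L))
    stop("week_index outside [13, 52]")
  cat
}

#' Count catalogue variables per category
#'
#' @param catalogue a `variable_catalogue`.
#' @return Named integer vector with counts for weather, soil and management;
#'   the counts sum to the number of catalogue entries.
#' @export
catalogue_counts <- function(catalogue) {
  vapply(c(weather = "weather", soil = "soil", management = "management"),
         function(cc) sum(catalogue$category == cc), integer(1))
}

## Column-name convention: W_/S_/M_ prefix for the category, optional
## _wk<13..52> suffix for weekly variables, optional _d<label> suffix for soil
## depth layers.
catalogue_from_names <- function(varnames) {
  category <- character(length(varnames))
  week <- rep(NA_integer_, length(varnames))
  depth <- rep(NA_character_, length(varnames))
  for (i in seq_along(varnames)) {
    v <- varnames[i]
    pre <- substr(v, 1L, 2L)
    category[i] <- switch(pre,
                          "W_" = "weather",
                          "S_" = "soil",
                          "M_" = "management",
                          stop("unknown category prefix in column '", v,
                               "' (expected W_, S_ or M_)"))
    mwk <- regmatches(v, regexpr("_wk([0-9]+)$", v))
    if (length(mwk) == 1L)
      week[i] <- as.integer(sub("_wk", "", mwk, fixed = TRUE))
    if (category[i] == "soil") {
      md <- regmatches(v, regexpr("_d([A-Za-z0-9_]+)$", v))
      if (length(md) == 1L) depth[i] <- sub("^_d", "", md)
    }
  }
  variable_catalogue(varnames, category, week, depth)
}

#' Construct a county-year sample panel
#'
#' A panel holds one row per (county, year) with a numeric explanatory matrix
#' aligned to a [variable_catalogue()] and an optional observed yield vector
#' in t/ha.
#'
#' @param county_id character vector of county identifiers.
#' @param year integer vector of years.
#' @param X numeric matrix, `length(county_id)` rows, one column per
#'   catalogue entry (column names must equal catalogue names).
#' @param y optional numeric yield vector (t/ha).
#' @param catalogue a `variable_catalogue`; inferred from `colnames(X)` when
#'   omitted.
#' @param normalized logical; `TRUE` when `X` already lives on the `[0, 1]`
#'   scale of a fitted [fit_scaler()] scaler.
#' @return An object of class `sample_panel`.
#' @export
sample_panel <- function(county_id, year, X, y = NULL, catalogue = NULL,
                         normalized = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(catalogue)) catalogue <- catalogue_from_names(colnames(X))
  p <- new_panel(data.frame(county_id = as.character(county_id),
                            year = as.integer(year),
                            stringsAsFactors = FALSE),
                 X, y, catalogue, normalized)
  validate_panel(p)
}

new_panel <- function(rows, X, y, catalogue, normalized) {
  structure(list(rows = rows, X = X, y = if (is.null(y)) NULL else as.numeric(y),
                 catalogue = catalogue, normalized = isTRUE(normalized)),
            class = "sample_panel")
}

validate_panel <- function(p) {
  key <- paste(p$rows$county_id, p$rows$year, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (county_id, year) pair: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (nrow(p$X) != nrow(p$rows))
    stop("X has ", nrow(p$X), " rows but panel has ", nrow(p$rows))
  if (ncol(p$X) != nrow(p$catalogue))
    stop("X has ", ncol(p$X), " columns but catalogue has ",
         nrow(p$catalogue), " entries")
  if (!identical(colnames(p$X), p$catalogue$name))
    stop("colnames(X) do not match catalogue names")
  if (!all(is.finite(p$X)))
    stop("non-finite value(s) in X")
  if (!is.null(p$y) && length(p$y) != nrow(p$rows))
    stop("y length does not match number of rows")
  p
}

#' @export
print.sample_panel <- function(x, ...) {
  cc <- catalogue_counts(x$catalogue)
  cat(sprintf(
    "sample_panel: %d rows (%d counties, years %s-%s), %d variables\n",
    nrow(x$rows), length(unique(x$rows$county_id)),
    min(x$rows$year), max(x$rows$year), ncol(x$X)))
  cat(sprintf("  weather %d | soil %d | management %d | yield: %s | %s\n",
              cc["weather"], cc["soil"], cc["management"],
              if (is.null(x$y)) "absent" else "present",
              if (x$normalized) "normalized" else "natural units"))
  invisible(x)
}

#' Number of samples in a panel
#' @param panel a `sample_panel`.
#' @return Integer row count.
#' @export
n_samples <- function(panel) nrow(panel$rows)

#' Read a county-year panel from CSV
#'
#' Expects a header `county_id,year[,yield],<variables...>` where variable
#' columns carry the category prefix `W_` (weather), `S_` (soil) or `M_`
#' (management), weekly variables the suffix `_wk<13..52>`, and soil depths
#' the suffix `_d<label>`. The yield column may be absent for prediction-only
#' panels.
#'
#' @param path path to a CSV file.
#' @return A `sample_panel`; row order is preserved.
#' @export
load_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in '", path, "'")
  need <- c("county_id", "year")
  if (!all(need %in% names(df)))
    stop("panel CSV must start with columns county_id, year")
  has_y <- "yield" %in% names(df)
  varnames <- setdiff(names(df), c("county_id", "year", "yield"))
  for (v in varnames) {
    col <- df[[v]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("non-numeric cell at row ", bad, ", column '", v, "'")
    }
  }
  X <- as.matrix(df[varnames])
  rownames(X) <- NULL
  sample_panel(df$county_id, df$year, X,
               y = if (has_y) df$yield else NULL)
}

#' Write a county-year panel to CSV
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p, f))` reproduces the
#' panel cell for cell.
#'
#' @param panel a `sample_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(county_id = panel$rows$county_id,
                   year = panel$rows$year, stringsAsFactors = FALSE)
  if (!is.null(panel$y)) df$yield <- panel$y
  df <- cbind(df, as.data.frame(panel$X, optional = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate sub-county grid values to a single county value
#'
#' Soil grids are averaged; weather grids use the median (robust to local
#' outliers); management data are recorded at county level already, so
#' aggregation is refused.
#'
#' @param grid_values numeric vector of sub-county cell values.
#' @param category `"soil"` or `"weather"`.
#' @return A single numeric county-level value.
#' @export
aggregate_to_county <- function(grid_values, category) {
  if (length(grid_values) == 0L) stop("empty grid: nothing to aggregate")
  if (anyNA(grid_values) || !all(is.finite(grid_values)))
    stop("non-finite value in grid cells")
  switch(match.arg(category, c("soil", "weather", "management")),
         soil = mean(grid_values),
         weather = stats::median(grid_values),
         management = stop("management variables are county-level; ",
                           "aggregation not applicable"))
}

#' Daily growing-degree-day contribution
#'
#' `max(0, (min(Tmax, cap) + max(Tmin, base)) / 2 - base)`, the standard
#' capped/floored GDD definition (defaults are the corn convention:
#' base 10 C, cap 30 C).
#'
#' @param tmax,tmin daily maximum / minimum temperature (C); vectorized.
#' @param base,cap base and cap temperatures (C).
#' @return Daily GDD contribution(s).
#' @export
gdd_daily <- function(tmax, tmin, base = 10, cap = 30) {
  pmax(0, (pmin(tmax, cap) + pmax(tmin, base)) / 2 - base)
}

#' Count rainy days
#' @param daily_precip vector of daily precipitation (mm).
#' @param threshold rain threshold in mm (default 1 mm).
#' @return Number of days with precipitation strictly above `threshold`.
#' @export
count_rainy_days <- function(daily_precip, threshold = 1) {
  sum(daily_precip > threshold)
}

#' Count heat-unit days
#' @param daily_tmax vector of daily maximum temperatures (C).
#' @param threshold heat threshold in C (default 30 C).
#' @return Number of days with Tmax strictly above `threshold`.
#' @export
count_heat_units <- function(daily_tmax, threshold = 30) {
  sum(daily_tmax > threshold)
}

#' Append derived agronomic features to a panel
#'
#' Supported recipes:
#' \describe{
#'   \item{`"gdd"`}{weekly growing degree days, `7 * gdd_daily()` evaluated on
#'     the weekly-mean Tmax/Tmin columns (`W_tmax_wk<w>` / `W_tmin_wk<w>`),
#'     appended as `W_gdd_wk<w>`.}
#'   \item{`"yield_trend"`}{per-county least-squares line of historical yield
#'     versus year, evaluated at each row's year; for every row only years
#'     strictly before that row's year enter the fit (no look-ahead), so the
#'     covariate is usable for true out-of-year prediction. Appended as
#'     `M_yield_trend` (management category, mirroring how yield-trend
#'     covariates stand in for genetic-improvement trends).}
#' }
#' Rainy-day counts and heat units are daily-resolution features; compute
#' them with [count_rainy_days()] / [count_heat_units()] while aggregating
#' daily station data, before the weekly panel is assembled.
#'
#' Existing columns are never modified.
#'
#' @param panel a `sample_panel` in natural units.
#' @param recipes character vector, subset of `c("gdd", "yield_trend")`.
#' @param history data frame `county_id, year, yield` of historical yields
#'   (required for `"yield_trend"`; at least 2 years strictly before every
#'   panel row's year, per county).
#' @param gdd_base,gdd_cap GDD base and cap temperatures (C).
#' @return The panel with derived columns appended to matrix and catalogue.
#' @export
derive_features <- function(panel, recipes, history = NULL,
                            gdd_base = 10, gdd_cap = 30) {
  stopifnot(all(recipes %in% c("gdd", "yield_trend")))
  X0 <- panel$X
  X <- X0
  cat <- panel$catalogue
  if ("gdd" %in% recipes) {
    tmax_cols <- grep("^W_tmax_wk[0-9]+$", colnames(X0), value = TRUE)
    if (length(tmax_cols) == 0L)
      stop("gdd recipe requires weekly W_tmax_wk*/W_tmin_wk* columns")
    for (tc in tmax_cols) {
      wk <- sub("^W_tmax_wk", "", tc)
      tn <- paste0("W_tmin_wk", wk)
      if (!tn %in% colnames(X0))
        stop("gdd recipe: missing ", tn, " to pair with ", tc)
      newname <- paste0("W_gdd_wk", wk)
      X <- cbind(X, 7 * gdd_daily(X0[, tc], X0[, tn], gdd_base, gdd_cap))
      colnames(X)[ncol(X)] <- newname
      cat <- rbind(cat, data.frame(name = newname, category = "weather",
                                   week = as.integer(wk),
                                   depth = NA_character_))
    }
  }
  if ("yield_trend" %in% recipes) {
    if (is.null(history)) stop("yield_trend recipe requires `history`")
    trend <- numeric(n_samples(panel))
    for (i in seq_len(n_samples(panel))) {
      cid <- panel$rows$county_id[i]
      yr <- panel$rows$year[i]
      h <- history[history$county_id == cid & history$year < yr, , drop = FALSE]
      if (nrow(h) < 2L)
        stop("yield_trend: fewer than 2 prior years of history for county '",
             cid, "' before ", yr)
      fit <- stats::lm.fit(cbind(1, h$year), h$yield)
      trend[i] <- fit$coefficients[1] + fit$coefficients[2] * yr
    }
    X <- cbind(X, M_yield_trend = trend)
    cat <- rbind(cat, data.frame(name = "M_yield_trend",
                                 category = "management",
                                 week = NA_integer_, depth = NA_character_))
  }
  class(cat) <- c("variable_catalogue", "data.frame")
  out <- new_panel(panel$rows, X, panel$y, validate_catalogue(cat),
                   panel$normalized)
  stopifnot(identical(out$X[, colnames(X0), drop = FALSE], X0))
  validate_panel(out)
}

#' Fit a min-max scaler on designated panel rows
#'
#' Learns per-variable (min, max) on the fit rows only, so that later rows
#' (e.g. a test year) are mapped with the training scale and may fall outside
#' `[0, 1]`; no clipping is ever applied.
#'
#' @param panel a `sample_panel` in natural units.
#' @param fit_rows integer row indices used to learn the ranges (default all).
#' @return An object of class `scaler`.
#' @export
fit_scaler <- function(panel, fit_rows = seq_len(n_samples(panel))) {
  if (length(fit_rows) == 0L) stop("fit_rows must be nonempty")
  Xf <- panel$X[fit_rows, , drop = FALSE]
  new_scaler(apply(Xf, 2, min), apply(Xf, 2, max))
}

#' Construct a scaler from explicit per-variable bounds
#' @param min,max named numeric vectors of per-variable minima and maxima
#'   (`max >= min` elementwise).
#' @return An object of class `scaler`.
#' @export
new_scaler <- function(min, max) {
  stopifnot(length(min) == length(max), all(max >= min))
  structure(list(min = min, max = max, names = names(min)), class = "scaler")
}

#' Apply a scaler: map each variable to (x - min) / (max - min)
#'
#' Constant variables (max == min on the fit rows) map to 0 everywhere by
#' convention, so catalogue indices stay stable; values outside the fit range
#' map outside `[0, 1]`.
#'
#' @param panel a `sample_panel` in natural units.
#' @param scaler a `scaler` covering all panel variables.
#' @return The normalized panel (`normalized = TRUE`).
#' @export
apply_scaler <- function(panel, scaler) {
  if (panel$normalized) stop("panel is already normalized")
  if (!identical(scaler$names, colnames(panel$X)))
    stop("scaler variables do not match panel variables")
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1  # constant column -> (x - min)/1 = 0
  Xn <- sweep(sweep(panel$X, 2, scaler$min, "-"), 2, rng, "/")
  new_panel(panel$rows, Xn, panel$y, panel$catalogue, normalized = TRUE)
}

#' Invert a scaler on a normalized matrix (or vector for one variable)
#' @param values normalized numeric matrix/vector.
#' @param scaler a `scaler`.
#' @param vars variable names to invert (default: `colnames(values)`).
#' @return Values on the original scale.
#' @export
invert_scaler <- function(values, scaler, vars = colnames(values)) {
  idx <- match(vars, scaler$names)
  if (anyNA(idx)) stop("unknown variable(s): ",
                       paste(vars[is.na(idx)], collapse = ", "))
  rng <- (scaler$max - scaler$min)[idx]
  if (is.matrix(values))
    sweep(sweep(values, 2, rng, "*"), 2, scaler$min[idx], "+")
  else values * rng + scaler$min[idx]
}

#' Build blocked spatio-temporal validation folds
#'
#' Three schemes:
#' \describe{
#'   \item{`"temporal_kblock"`}{distinct years are split into `n_folds + 1`
#'     near-equal contiguous blocks; fold *j* validates block *j + 1* and
#'     trains on all strictly earlier years (expanding window), giving
#'     `n_folds` folds in chronological order.}
#'   \item{`"leave_year_out"`}{every distinct year except the earliest is a
#'     validation fold; training = all strictly earlier years.}
#'   \item{`"spatial_holdout"`}{leave-one-group-out over county `groups`
#'     (e.g. states); `holdout` restricts to a single named group.}
#' }
#'
#' @param panel a `sample_panel`.
#' @param scheme `"temporal_kblock"`, `"leave_year_out"` or
#'   `"spatial_holdout"`.
#' @param n_folds number of temporal folds for `"temporal_kblock"`.
#' @param groups named character vector mapping `county_id` to a group label
#'   (spatial schemes).
#' @param holdout optional single group label to hold out.
#' @return An object of class `fold_scheme`: a list of folds, each with
#'   `train`, `validation` (row indices), `axis` and `label`.
#' @export
make_folds <- function(panel,
                       scheme = c("temporal_kblock", "leave_year_out",
                                  "spatial_holdout"),
                       n_folds = 4L, groups = NULL, holdout = NULL) {
  scheme <- match.arg(scheme)
  yrs <- panel$rows$year
  folds <- list()
  if (scheme %in% c("temporal_kblock", "leave_year_out")) {
    uy <- sort(unique(yrs))
    if (length(uy) < 2L) stop("temporal folds require >= 2 distinct years")
    if (scheme == "leave_year_out") {
      blocks <- as.list(uy[-1L])
    } else {
      if (n_folds + 1L > length(uy))
        stop("n_folds = ", n_folds, " requires at least ", n_folds + 1L,
             " distinct years (got ", length(uy), ")")
      cut_idx <- split(seq_along(uy),
                       cut(seq_along(uy), n_folds + 1L, labels = FALSE))
      blocks <- lapply(cut_idx[-1L], function(ii) uy[ii])
    }
    for (b in blocks) {
      val <- which(yrs %in% b)
      tr <- which(yrs < min(b))
      folds[[length(folds) + 1L]] <-
        list(train = tr, validation = val, axis = "temporal",
             label = paste0("years_", min(b), "_", max(b)))
    }
  } else {
    if (is.null(groups)) stop("spatial_holdout requires `groups`")
    g <- groups[panel$rows$county_id]
    if (anyNA(g)) stop("counties missing from `groups`: ",
                       paste(unique(panel$rows$county_id[is.na(g)]),
                             collapse = ", "))
    labs <- if (is.null(holdout)) sort(unique(g)) else holdout
    if (length(unique(g)) < 2L) stop("spatial folds require >= 2 groups")
    for (lab in labs) {
      if (!lab %in% g) stop("unknown holdout group '", lab, "'")
      folds[[length(folds) + 1L]] <-
        list(train = which(g != lab), validation = which(g == lab),
             axis = "spatial", label = paste0("group_", lab))
    }
  }
  fs <- structure(folds, class = "fold_scheme")
  validate_folds(fs, panel)
}

validate_folds <- function(fs, panel) {
  yrs <- panel$rows$year
  for (f in fs) {
    if (length(f$validation) == 0L) stop("empty validation fold")
    if (length(intersect(f$train, f$validation)) > 0L)
      stop("train and validation overlap in fold ", f$label)
    if (f$axis == "temporal" && length(f$train) > 0L &&
        max(yrs[f$train]) >= min(yrs[f$validation]))
      stop("temporal leakage in fold ", f$label)
    if (f$axis == "spatial") {
      cs <- panel$rows$county_id
      if (length(intersect(cs[f$train], cs[f$validation])) > 0L)
        stop("county appears on both sides of spatial fold ", f$label)
    }
  }
  fs
}

#' Concatenate fold schemes (e.g. temporal + spatial axes)
#' @param ... `fold_scheme` objects.
#' @return A combined `fold_scheme`.
#' @export
combine_folds <- function(...) {
  structure(do.call(c, lapply(list(...), unclass)), class = "fold_scheme")
}

#' @export
print.fold_scheme <- function(x, ...) {
  cat("fold_scheme with", length(x), "folds:\n")
  for (f in x)
    cat(sprintf("  [%s] %s: train %d / validation %d\n",
                f$axis, f$label, length(f$train), length(f$validation)))
  invisible(x)
}

#' Export a fold scheme as JSON
#' @param folds a `fold_scheme`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_folds <- function(folds, path) {
  jsonlite::write_json(
    lapply(folds, function(f)
      list(axis = f$axis, label = f$label,
           train_row_ids = f$train, validation_row_ids = f$validation)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Subset a panel by row indices
#' @param panel a `sample_panel`.
#' @param rows integer row indices.
#' @return The sub-panel with the same catalogue.
#' @export
subset_panel <- function(panel, rows) {
  new_panel(panel$rows[rows, , drop = FALSE],
            panel$X[rows, , drop = FALSE],
            if (is.null(panel$y)) NULL else panel$y[rows],
            panel$catalogue, panel$normalized)
}
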