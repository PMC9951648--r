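#' Regression coefficient of a target on a marker
#'
#' The workhorse of the forecast machinery: the expected change of the
#' predicted index per unit change of the marker,
#' `b = r * sd_target / sd_marker`, assembled from the descriptive
#' statistics and the correlation computed in the earlier stages.
#'
#' @param stats_marker,stats_target [describe()] results for the marker
#'   and the target.
#' @param corr A [correlate()] result relating the two traits (either
#'   argument order).
#' @return An object of class `"regression_coef"` with fields `marker`,
#'   `target`, `b`, `r_used`, `sd_target`, `sd_marker`.
#' @examples
#' # b = 0.9 * 62.8 / 5 = 11.3 kg of pre-slaughter weight
#' # per kg of birth weight
#' @export
regression_coefficient <- function(stats_marker, stats_target, corr) {
  stopifnot(inherits(stats_marker, "herd_desc"),
            inherits(stats_target, "herd_desc"),
            inherits(corr, "herd_cor"))
  ids <- c(ta_id(corr$trait_x), ta_id(corr$trait_y))
  mk <- ta(stats_marker$trait, stats_marker$age_months)
  tg <- ta(stats_target$trait, stats_target$age_months)
  if (!setequal(ids, c(ta_id(mk), ta_id(tg)))) {
    stop("correlation does not relate ", ta_id(mk), " and ", ta_id(tg),
         call. = FALSE)
  }
  if (stats_marker$sd == 0) {
    stop("degenerate marker: sd of ", ta_id(mk), " is zero",
         call. = FALSE)
  }
  structure(list(marker = mk, target = tg,
                 b = corr$r * stats_target$sd / stats_marker$sd,
                 r_used = corr$r, sd_target = stats_target$sd,
                 sd_marker = stats_marker$sd),
            class = "regression_coef")
}

#' A regression coefficient taken from a printed table
#'
#' Strict-replication constructor: wraps a published coefficient value
#' so it can drive [build_forecast_table()] directly, when reproducing a
#' printed table is wanted rather than recomputing `b` from data.
#'
#' @param b Coefficient value (target units per marker unit).
#' @param marker,target [ta()] pairs (or string ids).
#' @return A `"regression_coef"` whose `r_used` and dispersions are
#'   `NA`.
#' @export
printed_coefficient <- function(b, marker, target) {
  stopifnot(is.numeric(b), length(b) == 1)
  structure(list(marker = ta_parse(marker), target = ta_parse(target),
                 b = b, r_used = NA_real_, sd_target = NA_real_,
                 sd_marker = NA_real_),
            class = "regression_coef")
}

#' @export
print.regression_coef <- function(x, ...) {
  cat(sprintf("b(%s per %s) = %.4g%s\n", ta_id(x$target),
              ta_id(x$marker), x$b,
              if (is.na(x$r_used)) " [printed]"
              else sprintf(" (r = %.3f)", x$r_used)))
  invisible(x)
}

#' Build a forecast table for one marker
#'
#' A forecast table maps a grid of marker values, centred on the
#' (rounded) marker mean, to the predicted value of each target index
#' by the affine rule `predicted = anchor + b * (x - marker_mean)`,
#' where the anchor is the target mean.  This is the practitioner-facing
#' artefact of the workflow: a barn-door lookup table.
#'
#' @param marker_stats [describe()] result for the marker (or a list
#'   `list(trait, age_months, mean)` in strict-replication use).
#' @param targets List of entries `list(stats = <herd_desc or
#'   list(mean)>, coef = <regression_coef>)`, all sharing the marker.
#' @param half_width,step Grid extent around the rounded mean and grid
#'   step, in marker units (defaults 6 and 1, the conventional span).
#' @return An object of class `"forecast_table"`: `marker`,
#'   `marker_mean`, `grid`, and one row per target holding `b`,
#'   `anchor` and the `predicted` vector (full precision; rendering to
#'   one decimal happens in `print`/`format`).
#' @seealso [eval_forecast_table()], [forecast_animal()]
#' @export
build_forecast_table <- function(marker_stats, targets,
                                 half_width = 6, step = 1) {
  if (half_width <= 0 || step <= 0) {
    stop("grid half_width and step must be positive", call. = FALSE)
  }
  mk <- ta(marker_stats$trait, marker_stats$age_months)
  rows <- list()
  for (tg in targets) {
    stopifnot(inherits(tg$coef, "regression_coef"))
    if (ta_id(tg$coef$marker) != ta_id(mk)) {
      stop("coefficient for ", ta_id(tg$coef$target),
           " does not share the table marker ", ta_id(mk), call. = FALSE)
    }
    rows[[ta_id(tg$coef$target)]] <- list(
      b = tg$coef$b, anchor = tg$stats$mean, coef = tg$coef)
  }
  centre <- round_half_up(marker_stats$mean, 0)
  grid <- seq(centre - half_width, centre + half_width, by = step)
  for (t in names(rows)) {
    rows[[t]]$predicted <-
      rows[[t]]$anchor + rows[[t]]$b * (grid - marker_stats$mean)
  }
  structure(list(marker = mk, marker_mean = marker_stats$mean,
                 grid = grid, rows = rows),
            class = "forecast_table")
}

#' Evaluate a forecast table at a marker value
#'
#' `"linear"` interpolation evaluates the underlying affine rule
#' exactly (the grid resolution is then irrelevant); `"nearest"` reads
#' the nearest grid cell, as a barn user would.  A marker value outside
#' the grid in nearest mode triggers an extrapolation warning and falls
#' back to the affine rule.
#'
#' @param table A [build_forecast_table()] result.
#' @param target Target trait name; `NULL` for all rows.
#' @param x Marker value(s).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return Named numeric vector (targets) if `x` is scalar, else a
#'   matrix `x` by target.
#' @export
eval_forecast_table <- function(table, x, target = NULL,
                                interpolation = c("linear", "nearest")) {
  stopifnot(inherits(table, "forecast_table"))
  interpolation <- match.arg(interpolation)
  targets <- if (is.null(target)) names(table$rows) else target
  out <- matrix(NA_real_, length(x), length(targets),
                dimnames = list(NULL, targets))
  outside <- x < min(table$grid) | x > max(table$grid)
  if (interpolation == "nearest" && any(outside)) {
    warning("marker value outside the table grid; extrapolating from ",
            "the regression line", call. = FALSE)
  }
  for (t in targets) {
    row <- table$rows[[t]]
    if (is.null(row)) stop("no table row for target ", t, call. = FALSE)
    line <- row$anchor + row$b * (x - table$marker_mean)
    if (interpolation == "linear") {
      out[, t] <- line
    } else {
      idx <- vapply(x, function(v) which.min(abs(table$grid - v)),
                    integer(1))
      out[, t] <- ifelse(outside, line, row$predicted[idx])
    }
  }
  if (length(x) == 1L) out[1, ] else out
}

#' @export
print.forecast_table <- function(x, digits = 1, ...) {
  cat("Forecast table by", ta_label(x$marker), "\n")
  cat(sprintf("  marker mean %.1f; grid %s..%s\n", x$marker_mean,
              min(x$grid), max(x$grid)))
  cells <- t(vapply(x$rows, function(r)
    round_half_up(r$predicted, digits), numeric(length(x$grid))))
  dimnames(cells) <- list(names(x$rows), x$grid)
  b <- vapply(x$rows, function(r) r$b, numeric(1))
  print(cbind(b = round_half_up(b, 1), cells))
  invisible(x)
}

#' @export
format.forecast_table <- function(x, digits = 1, ...) {
  cells <- t(vapply(x$rows, function(r)
    round_half_up(r$predicted, digits), numeric(length(x$grid))))
  df <- data.frame(target = names(x$rows),
                   b = vapply(x$rows, function(r) r$b, numeric(1)),
                   anchor = vapply(x$rows, function(r) r$anchor,
                                   numeric(1)),
                   cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-(1:3)] <- as.character(x$grid)
  df
}

#' Combine per-marker forecasts by arithmetic averaging
#'
#' The multi-marker prediction for an animal is the unweighted
#' arithmetic mean, target by target, of the forecasts read from each
#' marker's table.
#'
#' @param per_marker Numeric matrix, markers in rows, targets in
#'   columns.
#' @return Named numeric vector of combined predictions.
#' @export
combine_forecasts <- function(per_marker) {
  stopifnot(is.matrix(per_marker))
  colMeans(per_marker)
}

#' Multi-marker forecast for one animal
#'
#' Reads each marker's forecast table at the animal's marker values and
#' combines them by arithmetic averaging.
#'
#' @param tables List of [build_forecast_table()] results, one per
#'   marker.
#' @param marker_values Named numeric vector of the animal's marker
#'   values, names being [ta()] string ids matching the tables.
#' @param interpolation Passed to [eval_forecast_table()].
#' @param animal_id Optional id carried into the result.
#' @return An object of class `"marker_forecast"`: `animal_id`,
#'   `per_marker` (matrix markers x targets) and `combined`.
#' @export
forecast_animal <- function(tables, marker_values,
                            interpolation = c("linear", "nearest"),
                            animal_id = NA_character_) {
  interpolation <- match.arg(interpolation)
  tab_ids <- vapply(tables, function(t) ta_id(t$marker), character(1))
  names(tables) <- tab_ids
  miss <- setdiff(names(marker_values), tab_ids)
  if (length(miss)) {
    stop("no forecast table for marker(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  targets <- names(tables[[1]]$rows)
  per <- matrix(NA_real_, length(marker_values), length(targets),
                dimnames = list(names(marker_values), targets))
  for (m in names(marker_values)) {
    per[m, ] <- eval_forecast_table(tables[[m]], marker_values[[m]],
                                    interpolation = interpolation)
  }
  structure(list(animal_id = animal_id, per_marker = per,
                 combined = combine_forecasts(per)),
            class = "marker_forecast")
}

#' @export
print.marker_forecast <- function(x, digits = 1, ...) {
  if (!is.na(x$animal_id)) cat("Animal", x$animal_id, "\n")
  m <- round_half_up(cbind(x$per_marker,
                           combined = x$combined), digits)
  print(t(m))
  invisible(x)
}

#' Forecast accuracy
#'
#' The agreement between a forecast and the realized value, as a
#' percentage of the forecast: `100 * (1 - |forecast - actual| /
#' forecast)`.  Reported rounded to whole percent (half up) in tables;
#' this function returns full precision.
#'
#' @param forecast,actual Positive numeric vectors.
#' @return Numeric vector of accuracies (percent, full precision).
#' @examples
#' forecast_accuracy(428.6, 420.3)                 # 98.06...
#' round_half_up(forecast_accuracy(234.1, 210.3))  # 90
#' @export
forecast_accuracy <- function(forecast, actual) {
  if (any(forecast <= 0) || any(actual <= 0)) {
    stop("forecast and actual must be positive", call. = FALSE)
  }
  100 * (1 - abs(forecast - actual) / forecast)
}

#' Out-of-farm validation of the forecast method
#'
#' The approbation procedure: build forecast tables from a training
#' herd (or take them as given), forecast every test animal with
#' complete markers, and compare the mean forecast against the mean
#' realized slaughter value per target.  Farm-level accuracy is
#' [forecast_accuracy()] applied to those aggregated means — the way
#' approbation results are reported — with the mean per-animal accuracy
#' alongside.
#'
#' @param train A `herd_dataset` with slaughter records (ignored when
#'   `external_tables` is given).
#' @param test A `herd_dataset` with slaughter records to validate
#'   against.
#' @param markers List of [ta()] marker pairs.
#' @param targets Slaughter trait names.
#' @param external_tables Optional list of forecast tables to use
#'   instead of fitting on `train` (e.g. another farm's tables).
#' @param farm Label carried into the report.
#' @param ... Passed to [herdcast()] when fitting on `train`.
#' @return A data frame of class `"accuracy_report"`, one row per
#'   target: `farm`, `target`, `n`, `forecast_mean`, `forecast_sem`,
#'   `actual_mean`, `actual_sem`, `accuracy_pct`,
#'   `accuracy_pct_rounded`, `per_animal_accuracy`.
#' @export
approbate <- function(train = NULL, test, markers = default_markers(),
                      targets = default_targets(),
                      external_tables = NULL, farm = "test farm", ...) {
  if (is.null(external_tables)) {
    if (is.null(train)) {
      stop("either train or external_tables must be supplied",
           call. = FALSE)
    }
    fit <- herdcast(train, markers = markers, targets = targets,
                    screen = FALSE, ...)
    tables <- fit$tables
  } else {
    tables <- external_tables
  }
  if (nrow(test$slaughter) == 0) {
    stop("test herd has no slaughter records to validate against",
         call. = FALSE)
  }
  fc <- predict_with_tables(tables, test)
  if (nrow(fc) == 0) {
    stop("no test animal has complete marker values", call. = FALSE)
  }
  rows <- list()
  for (t in intersect(names(tables[[1]]$rows), targets)) {
    actual <- herd_values(test, ta(t))
    ids <- intersect(rownames(fc), names(actual))
    if (length(ids) < 2) {
      stop("fewer than 2 test animals with forecast and slaughter ",
           "record for ", t, call. = FALSE)
    }
    f <- fc[ids, t]; a <- actual[ids]
    acc <- forecast_accuracy(mean(f), mean(a))
    rows[[t]] <- data.frame(
      farm = farm, target = t, n = length(ids),
      forecast_mean = mean(f),
      forecast_sem = stats::sd(f) / sqrt(length(f)),
      actual_mean = mean(a),
      actual_sem = stats::sd(a) / sqrt(length(a)),
      accuracy_pct = acc,
      accuracy_pct_rounded = round_half_up(acc),
      per_animal_accuracy = mean(forecast_accuracy(f, a)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("accuracy_report", class(out))
  out
}

# combined forecasts for every herd animal with complete markers;
# returns a matrix animals x targets
predict_with_tables <- function(tables, herd,
                                interpolation = "linear") {
  tab_ids <- vapply(tables, function(t) ta_id(t$marker), character(1))
  vals <- lapply(tab_ids, function(id) herd_values(herd, id))
  ids <- Reduce(intersect, lapply(vals, names))
  targets <- names(tables[[1]]$rows)
  acc <- matrix(0, length(ids), length(targets),
                dimnames = list(ids, targets))
  for (i in seq_along(tables)) {
    p <- eval_forecast_table(tables[[i]], vals[[i]][ids],
                             interpolation = interpolation)
    if (!is.matrix(p)) p <- matrix(p, nrow = 1,
                                   dimnames = list(NULL, names(p)))
    acc <- acc + p[, targets, drop = FALSE]
  }
  acc / length(tables)
}
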