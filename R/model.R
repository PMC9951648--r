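#' Fit the meat-productivity forecast model to a herd
#'
#' One call runs the estimation stages of the prognosis workflow on a
#' herd with slaughter records: descriptive biometry of markers and
#' targets, reliability-tested marker-target correlations, optional
#' marker screening, regression coefficients
#' `b = r * sd_target / sd_marker`, and the per-marker forecast tables.
#' The fitted object predicts slaughter indices for new animals from
#' their birth-time markers, each prediction being the arithmetic mean
#' of the per-marker regression forecasts.
#'
#' @param data A [herd_dataset()] with slaughter records.
#' @param markers List of candidate [ta()] marker pairs (default: dam
#'   live weight, birth live weight, birth withers height).
#' @param targets Slaughter trait names to predict.
#' @param alpha Significance level of the correlation reliability test.
#' @param screen Either `FALSE` (keep all markers), or a list with
#'   elements `threshold` and `require_reliable` passed to
#'   [screen_markers()].
#' @param half_width,step Forecast-table grid parameters, in marker
#'   units.
#' @return An object of class `"herdcast"` with components `call`,
#'   `markers`, `targets`, `marker_stats`, `target_stats`,
#'   `correlations`, `coefficients` (list), `tables`
#'   (per-marker [build_forecast_table()] results), `n`, and the
#'   training `data`.
#' @seealso [predict.herdcast()], [approbate()]
#' @examples
#' herd <- generate_herd(default_herd_config(150, seed = 42))
#' fit <- herdcast(herd)
#' coef(fit)
#' predict(fit, newdata = data.frame(dam_live_weight_kg = 521,
#'                                   `live_weight_kg@0` = 27,
#'                                   `height_withers_cm@0` = 70,
#'                                   check.names = FALSE))
#' @export
herdcast <- function(data, markers = default_markers(),
                     targets = default_targets(), alpha = 0.05,
                     screen = FALSE, half_width = 6, step = 1) {
  stopifnot(inherits(data, "herd_dataset"))
  if (nrow(data$slaughter) == 0) {
    stop("herdcast needs slaughter records to fit against",
         call. = FALSE)
  }
  markers <- lapply(markers, ta_parse)
  mset <- NULL
  if (!isFALSE(screen)) {
    if (isTRUE(screen)) screen <- list()
    mset <- screen_markers(
      data, candidates = markers, targets = targets,
      threshold = if (is.null(screen$threshold)) 0.3
                  else screen$threshold,
      require_reliable = if (is.null(screen$require_reliable)) TRUE
                         else screen$require_reliable,
      alpha = alpha)
    markers <- mset$markers
    if (!length(markers)) {
      stop("no marker survived screening; relax the threshold",
           call. = FALSE)
    }
  }
  mids <- vapply(markers, ta_id, character(1))
  marker_stats <- lapply(markers, function(m)
    describe(data, m$trait, m$age))
  names(marker_stats) <- mids
  target_stats <- lapply(targets, function(t) describe(data, t))
  names(target_stats) <- targets

  correlations <- list()
  coefficients <- list()
  tables <- list()
  for (i in seq_along(markers)) {
    m <- markers[[i]]
    rows <- list()
    for (t in targets) {
      est <- correlate(data, m, ta(t), alpha)
      correlations[[paste(mids[i], t, sep = " ~ ")]] <- est
      cf <- regression_coefficient(marker_stats[[i]],
                                   target_stats[[t]], est)
      coefficients[[paste(mids[i], t, sep = " ~ ")]] <- cf
      rows[[t]] <- list(stats = target_stats[[t]], coef = cf)
    }
    tables[[mids[i]]] <- build_forecast_table(
      marker_stats[[i]], rows, half_width = half_width, step = step)
  }

  structure(list(call = match.call(), markers = markers,
                 targets = targets, marker_set = mset,
                 marker_stats = marker_stats,
                 target_stats = target_stats,
                 correlations = correlations,
                 coefficients = coefficients, tables = tables,
                 n = nrow(data$slaughter), data = data),
            class = "herdcast")
}

#' @export
print.herdcast <- function(x, ...) {
  cat("Meat-productivity forecast model\n")
  cat("  fitted on", x$n, "slaughtered animals\n")
  cat("  markers:", paste(vapply(x$markers, ta_id, character(1)),
                          collapse = ", "), "\n")
  cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  cat("Regression coefficients (target units per marker unit):\n")
  print(round_half_up(stats::coef(x), 2))
  invisible(x)
}

#' @export
coef.herdcast <- function(object, ...) {
  mids <- vapply(object$markers, ta_id, character(1))
  out <- matrix(NA_real_, length(object$targets), length(mids),
                dimnames = list(object$targets, mids))
  for (cf in object$coefficients) {
    out[ta_id(cf$target), ta_id(cf$marker)] <- cf$b
  }
  out
}

#' @export
summary.herdcast <- function(object, ...) {
  mids <- vapply(object$markers, ta_id, character(1))
  cors <- t(vapply(object$correlations, function(e)
    c(r = e$r, m_r = e$m_r, t = e$t_stat, reliable = e$reliable,
      n = e$n), numeric(5)))
  res <- stats::residuals(object)
  structure(list(call = object$call, n = object$n, markers = mids,
                 targets = object$targets,
                 marker_stats = object$marker_stats,
                 target_stats = object$target_stats,
                 correlations = cors, b = stats::coef(object),
                 resid_summary = if (nrow(res)) apply(res, 2, summary)),
            class = "summary.herdcast")
}

#' @export
print.summary.herdcast <- function(x, ...) {
  cat("Meat-productivity forecast model (n =", x$n, "slaughtered)\n\n")
  cat("Marker biometry (mean ± sem; sd):\n")
  for (s in x$marker_stats) print(s)
  cat("\nTarget biometry:\n")
  for (s in x$target_stats) print(s)
  cat("\nMarker-target correlations:\n")
  print(round(x$correlations, 3))
  cat("\nRegression coefficients b = r * sd_y / sd_x:\n")
  print(round_half_up(x$b, 2))
  if (!is.null(x$resid_summary)) {
    cat("\nTraining residuals (actual - combined forecast):\n")
    print(round(x$resid_summary, 2))
  }
  invisible(x)
}

#' Predict slaughter indices from birth-time markers
#'
#' @param object A fitted [herdcast()] model.
#' @param newdata A `herd_dataset`, or a data frame whose columns are
#'   the marker string ids (one row per animal).  Defaults to the
#'   training herd.
#' @param type `"combined"` for the arithmetic-mean prediction (a
#'   matrix animals x targets) or `"per_marker"` for the underlying
#'   [forecast_animal()] objects.
#' @param interpolation `"linear"` (evaluate the regression line
#'   exactly) or `"nearest"` (read the nearest table cell).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.herdcast <- function(object, newdata = NULL,
                             type = c("combined", "per_marker"),
                             interpolation = "linear", ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  mids <- vapply(object$markers, ta_id, character(1))
  if (inherits(newdata, "herd_dataset")) {
    if (type == "combined") {
      return(predict_with_tables(object$tables, newdata,
                                 interpolation = interpolation))
    }
    vals <- lapply(mids, function(id) herd_values(newdata, id))
    ids <- Reduce(intersect, lapply(vals, names))
    return(lapply(stats::setNames(ids, ids), function(a)
      forecast_animal(object$tables,
                      stats::setNames(vapply(vals, `[[`, 0, a), mids),
                      interpolation = interpolation, animal_id = a)))
  }
  newdata <- as.data.frame(newdata, check.names = FALSE)
  miss <- setdiff(mids, names(newdata))
  if (length(miss)) {
    stop("newdata lacks marker column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fcs <- lapply(seq_len(nrow(newdata)), function(i)
    forecast_animal(object$tables,
                    stats::setNames(as.numeric(newdata[i, mids]), mids),
                    interpolation = interpolation,
                    animal_id = rownames(newdata)[i]))
  if (type == "per_marker") return(fcs)
  out <- t(vapply(fcs, function(f) f$combined,
                  numeric(length(object$targets))))
  rownames(out) <- rownames(newdata)
  out
}

#' @export
fitted.herdcast <- function(object, ...) {
  predict.herdcast(object)
}

#' @export
residuals.herdcast <- function(object, ...) {
  fit <- predict.herdcast(object)
  out <- matrix(NA_real_, nrow(fit), ncol(fit),
                dimnames = dimnames(fit))
  for (t in colnames(fit)) {
    actual <- herd_values(object$data, ta(t))
    ids <- intersect(rownames(fit), names(actual))
    out[ids, t] <- actual[ids] - fit[ids, t]
  }
  out[rowSums(!is.na(out)) > 0, , drop = FALSE]
}

#' Plot a fitted forecast model
#'
#' Scatter of one marker against one target over the training animals,
#' with the forecast-table regression line through
#' (marker mean, target mean).
#'
#' @param x A fitted [herdcast()] model.
#' @param marker Marker string id (default: first fitted marker).
#' @param target Target trait (default: first target).
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.herdcast <- function(x, marker = NULL, target = NULL, ...) {
  mids <- vapply(x$markers, ta_id, character(1))
  marker <- if (is.null(marker)) mids[1] else marker
  target <- if (is.null(target)) x$targets[1] else target
  mv <- herd_values(x$data, marker)
  tv <- herd_values(x$data, ta(target))
  ids <- intersect(names(mv), names(tv))
  graphics::plot(mv[ids], tv[ids],
                 xlab = ta_label(ta_parse(marker)),
                 ylab = ta_label(ta(target)),
                 main = "Forecast regression", ...)
  cf <- x$coefficients[[paste(marker, target, sep = " ~ ")]]
  graphics::abline(a = x$target_stats[[target]]$mean -
                     cf$b * x$marker_stats[[marker]]$mean,
                   b = cf$b, col = "red3", lwd = 2)
  invisible(x)
}
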