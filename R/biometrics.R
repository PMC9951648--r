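#' Descriptive biometry of one trait
#'
#' The first stage of the prognosis workflow: mean, error of the mean
#' (sem, the classical "m" in "X +/- m") and standard deviation
#' (denominator n - 1) of a trait at one age.
#'
#' @param x A `herd_dataset`.
#' @param trait Trait name (longitudinal, `"dam_live_weight_kg"`, or a
#'   slaughter index).
#' @param age Age in months for longitudinal traits; ignored otherwise.
#' @return An object of class `"herd_desc"` with fields `trait`,
#'   `age_months`, `n`, `mean`, `sd`, `sem`.
#' @examples
#' herd <- generate_herd(default_herd_config(50, seed = 1))
#' describe(herd, "live_weight_kg", 0)
#' @export
describe <- function(x, trait, age = NA) {
  pair <- ta(trait, age)
  v <- herd_values(x, pair)
  if (length(v) < 2) {
    stop("need at least 2 observations of ", ta_id(pair),
         ", got ", length(v), call. = FALSE)
  }
  s <- stats::sd(v)
  structure(list(trait = pair$trait, age_months = pair$age,
                 n = length(v), mean = mean(v), sd = s,
                 sem = s / sqrt(length(v))),
            class = "herd_desc")
}

#' @export
print.herd_desc <- function(x, digits = 1, ...) {
  cat(sprintf("%s: %s ± %s (sd %s, n = %d)\n",
              ta_label(ta(x$trait, x$age_months)),
              formatC(round_half_up(x$mean, digits), format = "f",
                      digits = digits),
              formatC(round_half_up(x$sem, digits + 1), format = "f",
                      digits = digits + 1),
              formatC(round_half_up(x$sd, digits + 1), format = "f",
                      digits = digits + 1),
              x$n))
  invisible(x)
}

#' Pearson correlation with its reliability test
#'
#' Computes the Pearson correlation between two traits on the animals
#' observed for both (complete-case pairing), together with the
#' classical zootechnical error of the correlation coefficient
#' m_r = (1 - r^2) / sqrt(n - 2) and the reliability criterion
#' t = r / m_r, compared against the two-sided Student critical value
#' at level `alpha` with n - 2 degrees of freedom.  A coefficient is
#' "reliable" (the asterisked entries of correlation tables) when
#' |t| meets the critical value; a perfect correlation (m_r = 0) is
#' reliable by convention.
#'
#' @param x A `herd_dataset`.
#' @param pair_x,pair_y [ta()] trait/age pairs (or string ids).
#' @param alpha Significance level of the reliability test.
#' @return An object of class `"herd_cor"` with fields `trait_x`,
#'   `trait_y`, `n`, `r`, `m_r`, `t_stat`, `reliable`, `alpha`.
#' @examples
#' herd <- generate_herd(default_herd_config(100, seed = 1))
#' correlate(herd, ta("live_weight_kg", 0), ta("live_weight_kg", 18))
#' @export
correlate <- function(x, pair_x, pair_y, alpha = 0.05) {
  pair_x <- ta_parse(pair_x)
  pair_y <- ta_parse(pair_y)
  vx <- herd_values(x, pair_x)
  vy <- herd_values(x, pair_y)
  common <- intersect(names(vx), names(vy))
  n <- length(common)
  if (n < 4) {
    stop("need at least 4 paired observations of ", ta_id(pair_x),
         " and ", ta_id(pair_y), ", got ", n, call. = FALSE)
  }
  vx <- vx[common]; vy <- vy[common]
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
    stop("correlation undefined: zero variance in ",
         if (stats::sd(vx) == 0) ta_id(pair_x) else ta_id(pair_y),
         call. = FALSE)
  }
  r <- stats::cor(vx, vy)
  m_r <- (1 - r^2) / sqrt(n - 2)
  t_stat <- if (m_r > 0) r / m_r else Inf * sign(r)
  crit <- stats::qt(1 - alpha / 2, df = n - 2)
  structure(list(trait_x = pair_x, trait_y = pair_y, n = n, r = r,
                 m_r = m_r, t_stat = t_stat,
                 reliable = is.infinite(t_stat) || abs(t_stat) >= crit,
                 alpha = alpha),
            class = "herd_cor")
}

# "0.8 +/- 0.06 *" rendering used in correlation tables
format_cor <- function(r, m_r, reliable) {
  sprintf("%.1f ± %.2g%s", round_half_up(r, 1),
          round_half_up(m_r, 2), ifelse(reliable, " *", ""))
}

#' @export
print.herd_cor <- function(x, ...) {
  cat(sprintf("r(%s, %s) = %s  (n = %d, t = %.2f)\n",
              ta_id(x$trait_x), ta_id(x$trait_y),
              format_cor(x$r, x$m_r, x$reliable), x$n, x$t_stat))
  invisible(x)
}

#' Correlation tables across ages or between measurements
#'
#' Stage two of the workflow.  With `axis = "ages"` it computes the
#' correlation of one trait (live weight by default) between every pair
#' of measurement ages; with `axis = "measurements"` the correlations
#' between every pair of body measurements within each age.  With a
#' grouping, the table is computed per sire line or bloodline as well
#' as pooled.
#'
#' @param x A `herd_dataset`.
#' @param axis `"ages"` or `"measurements"`.
#' @param grouping `"all"`, `"sire_line"` or `"bloodline"`.
#' @param trait Trait used for the age-pair table.
#' @param alpha Reliability level, passed to [correlate()].
#' @return A data frame of class `"correlation_table"` with one row per
#'   (group, pair): columns `group`, `x`, `y`, `n`, `r`, `m_r`,
#'   `t_stat`, `reliable`, `label`.
#' @seealso [cor_matrix()] to reshape one group into a symmetric matrix.
#' @export
correlation_table <- function(x, axis = c("ages", "measurements"),
                              grouping = c("all", "sire_line",
                                           "bloodline"),
                              trait = "live_weight_kg", alpha = 0.05) {
  axis <- match.arg(axis)
  grouping <- match.arg(grouping)
  groups <- list(pooled = x)
  if (grouping != "all") {
    for (lev in unique(x$animals[[grouping]])) {
      groups[[lev]] <- subset_by_group(x, grouping, lev)
    }
  }
  present <- unique(x$observations[, c("trait", "age_months")])
  rows <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    if (axis == "ages") {
      ages <- sort(unique(present$age_months[present$trait == trait]))
      pairs <- utils::combn(ages, 2, simplify = FALSE)
      for (p in pairs) {
        est <- correlate(sub, ta(trait, p[1]), ta(trait, p[2]), alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, x = ta_id(est$trait_x), y = ta_id(est$trait_y),
          n = est$n, r = est$r, m_r = est$m_r, t_stat = est$t_stat,
          reliable = est$reliable,
          label = format_cor(est$r, est$m_r, est$reliable),
          stringsAsFactors = FALSE)
      }
    } else {
      meas <- setdiff(longitudinal_traits(), "live_weight_kg")
      for (a in sort(unique(present$age_months))) {
        here <- intersect(meas,
                          present$trait[present$age_months == a])
        if (length(here) < 2) next
        pairs <- utils::combn(here, 2, simplify = FALSE)
        for (p in pairs) {
          est <- correlate(sub, ta(p[1], a), ta(p[2], a), alpha)
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, x = ta_id(est$trait_x), y = ta_id(est$trait_y),
            n = est$n, r = est$r, m_r = est$m_r, t_stat = est$t_stat,
            reliable = est$reliable,
            label = format_cor(est$r, est$m_r, est$reliable),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("correlation_table", class(out))
  attr(out, "axis") <- axis
  attr(out, "grouping") <- grouping
  out
}

#' Reshape one group of a correlation table into a symmetric matrix
#'
#' @param tbl A [correlation_table()].
#' @param group Group label (default `"pooled"`).
#' @param value Which column to spread (`"r"` or `"label"`).
#' @return A symmetric matrix with unit (or `"-"`) diagonal.
#' @export
cor_matrix <- function(tbl, group = "pooled", value = "r") {
  sub <- tbl[tbl$group == group, , drop = FALSE]
  if (!nrow(sub)) stop("no such group: ", group, call. = FALSE)
  vars <- unique(c(sub$x, sub$y))
  m <- matrix(if (value == "r") 1 else "-", length(vars), length(vars),
              dimnames = list(vars, vars))
  for (i in seq_len(nrow(sub))) {
    m[sub$x[i], sub$y[i]] <- sub[[value]][i]
    m[sub$y[i], sub$x[i]] <- sub[[value]][i]
  }
  m
}

#' Screen candidate marker traits against slaughter targets
#'
#' Stage three: a candidate trait is retained as a forecast marker when
#' its correlation with *every* target index clears the threshold and
#' (optionally) is reliable.  The default candidates are the three
#' birth-time traits of [default_markers()].
#'
#' @param x A `herd_dataset` with slaughter records.
#' @param candidates List of [ta()] pairs to screen.
#' @param targets Slaughter trait names.
#' @param threshold Minimum correlation with each target.  The default
#'   0.3 admits moderately correlated ancestral traits such as dam live
#'   weight (r around 0.4) while excluding noise-level associations.
#' @param require_reliable Require the reliability criterion as well.
#' @param alpha Reliability level.
#' @return An object of class `"marker_set"`: the retained markers, the
#'   targets, the screening rule and the full screening table.  An
#'   empty result is returned with a warning, not an error.
#' @export
screen_markers <- function(x, candidates = default_markers(),
                           targets = default_targets(), threshold = 0.3,
                           require_reliable = TRUE, alpha = 0.05) {
  rows <- list()
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    cand <- ta_parse(candidates[[i]])
    ok <- TRUE
    for (tgt in targets) {
      est <- correlate(x, cand, ta(tgt), alpha)
      pass <- est$r >= threshold && (!require_reliable || est$reliable)
      ok <- ok && pass
      rows[[length(rows) + 1L]] <- data.frame(
        marker = ta_id(cand), target = tgt, n = est$n, r = est$r,
        m_r = est$m_r, reliable = est$reliable, passes = pass,
        stringsAsFactors = FALSE)
    }
    keep[i] <- ok
  }
  if (!any(keep)) {
    warning("no candidate marker passed the screen (threshold ",
            threshold, ")", call. = FALSE)
  }
  structure(list(markers = lapply(candidates[keep], ta_parse),
                 targets = targets,
                 rule = list(threshold = threshold,
                             require_reliable = require_reliable,
                             alpha = alpha),
                 screen = do.call(rbind, rows)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("Marker set:", length(x$markers), "of",
      length(unique(x$screen$marker)), "candidates retained",
      sprintf("(r >= %s with %d targets%s)\n", x$rule$threshold,
              length(x$targets),
              if (x$rule$require_reliable) ", reliable" else ""))
  for (m in x$markers) cat("  -", ta_label(m), "\n")
  invisible(x)
}
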