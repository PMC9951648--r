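#' Heritability from dam-offspring resemblance
#'
#' Estimates the heritability of a trait as twice the Pearson
#' correlation between the dam phenotype (the `dam_live_weight_kg`
#' field) and the offspring trait value, the classical
#' parent-offspring doubling.  Raw values of `2 r` outside `[0, 1]`
#' are clipped with a warning: phenotypic resemblance can exceed the
#' additive bound through common environment or sampling noise.
#'
#' @param x A `herd_dataset` with dam values.
#' @param trait,age Offspring trait and age (default live weight at
#'   birth).
#' @param alpha Reliability level for the underlying correlation.
#' @return An object of class `"heritability"`: `trait`, `age_months`,
#'   `h2`, `h2_raw`, `r_parent_offspring`, `n` and the underlying
#'   [correlate()] estimate.
#' @export
estimate_heritability <- function(x, trait = "live_weight_kg", age = 0,
                                  alpha = 0.05) {
  est <- correlate(x, ta("dam_live_weight_kg"), ta(trait, age), alpha)
  h2_raw <- 2 * est$r
  h2 <- min(max(h2_raw, 0), 1)
  if (h2 != h2_raw) {
    warning(sprintf("2r = %.3f outside [0, 1]; clipped to %.3f",
                    h2_raw, h2), call. = FALSE)
  }
  structure(list(trait = trait, age_months = est$trait_y$age, h2 = h2,
                 h2_raw = h2_raw, r_parent_offspring = est$r,
                 n = est$n, corr = est),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("h2(%s) = %.2f  (dam-offspring r = %.3f%s, n = %d)\n",
              ta_id(ta(x$trait, x$age_months)), x$h2,
              x$r_parent_offspring,
              if (x$corr$reliable) ", reliable" else "", x$n))
  invisible(x)
}

#' Selection differential
#'
#' The superiority of the selected parents over the herd:
#' mean(selected) - mean(all), in trait units.  Parents are chosen
#' either as the top fraction of the trait distribution or as an
#' explicit set of animal ids.  Selecting every animal yields a
#' differential of zero (no selection); an empty selection is an error.
#'
#' @param x A `herd_dataset`.
#' @param trait,age Trait and age.
#' @param top_fraction Fraction of the herd to select from the top
#'   (e.g. 0.2 keeps the best fifth).
#' @param parents Alternatively, a character vector of selected
#'   animal ids.
#' @return The selection differential (numeric scalar, trait units).
#' @export
selection_differential <- function(x, trait = "live_weight_kg", age = 0,
                                   top_fraction = NULL, parents = NULL) {
  v <- herd_values(x, ta(trait, age))
  if (!length(v)) stop("no values for the trait", call. = FALSE)
  if (is.null(top_fraction) == is.null(parents)) {
    stop("supply exactly one of top_fraction or parents", call. = FALSE)
  }
  if (!is.null(top_fraction)) {
    if (top_fraction <= 0 || top_fraction > 1) {
      stop("top_fraction must be in (0, 1]", call. = FALSE)
    }
    k <- max(1L, floor(length(v) * top_fraction))
    sel <- sort(v, decreasing = TRUE)[seq_len(k)]
  } else {
    sel <- v[intersect(parents, names(v))]
    if (!length(sel)) stop("selected parent set is empty", call. = FALSE)
  }
  mean(sel) - mean(v)
}

#' Selection effect (response to selection)
#'
#' The breeder's equation: the expected per-generation change of a
#' trait is the selection differential times the heritability,
#' `effect = S * h2`.
#'
#' @param differential Selection differential, trait units.
#' @param h2 Heritability: a number in `[0, 1]` or an
#'   [estimate_heritability()] result.
#' @param trait Trait label carried into the result.
#' @return An object of class `"selection_effect"`: `trait`,
#'   `selection_differential`, `h2_used`, `effect_per_generation`.
#' @export
selection_effect <- function(differential, h2,
                             trait = "live_weight_kg") {
  if (inherits(h2, "heritability")) {
    trait <- h2$trait
    h2 <- h2$h2
  }
  if (!is.numeric(h2) || h2 < 0 || h2 > 1) {
    stop("h2 must be in [0, 1]", call. = FALSE)
  }
  structure(list(trait = trait, selection_differential = differential,
                 h2_used = h2,
                 effect_per_generation = differential * h2),
            class = "selection_effect")
}

#' @export
print.selection_effect <- function(x, ...) {
  cat(sprintf("Selection effect on %s: S = %.2f, h2 = %.2f -> %+.2f per generation\n",
              x$trait, x$selection_differential, x$h2_used,
              x$effect_per_generation))
  invisible(x)
}

#' Propagate a live-weight selection effect to a slaughter index
#'
#' With the regression coefficient of a slaughter index on live weight
#' (units of index per kg), the expected per-generation gain of the
#' index is proportional to the live-weight gain:
#' `effect_target = b * effect_liveweight`.
#'
#' @param effect A [selection_effect()] for live weight.
#' @param coef A `"regression_coef"` whose marker is live weight (any
#'   age) or pre-slaughter mass, and whose target is a slaughter index.
#' @return An object of class `"propagated_effect"`: `source_trait`,
#'   `target`, `b`, `effect_target`.
#' @export
propagate_effect <- function(effect, coef) {
  stopifnot(inherits(effect, "selection_effect"),
            inherits(coef, "regression_coef"))
  if (!coef$marker$trait %in% c("live_weight_kg",
                                "pre_slaughter_mass_kg")) {
    stop("coefficient marker must be live weight, got ",
         ta_id(coef$marker), call. = FALSE)
  }
  if (effect$trait != "live_weight_kg") {
    stop("selection effect must be on live weight, got ", effect$trait,
         call. = FALSE)
  }
  structure(list(source_trait = effect$trait,
                 target = ta_id(coef$target), b = coef$b,
                 effect_target = coef$b * effect$effect_per_generation),
            class = "propagated_effect")
}

#' @export
print.propagated_effect <- function(x, ...) {
  cat(sprintf("Propagated effect: %s %+.2f per generation (b = %.3f per kg live weight)\n",
              x$target, x$effect_target, x$b))
  invisible(x)
}
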