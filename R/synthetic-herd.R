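#' Configure the synthetic-herd generator
#'
#' The generator draws the longitudinal traits of each animal from a
#' joint Gaussian distribution on the raw measurement scale (truncated
#' three standard deviations below the mean so that masses and
#' measurements stay positive) and then produces the slaughter indices
#' as linear functions of the three birth-time markers plus an
#' independent Gaussian residual.
#'
#' @param n_animals Number of animals to simulate.
#' @param seed Optional integer seed; with a seed the generator is fully
#'   deterministic.
#' @param vars Data frame describing the longitudinal variables, with
#'   columns `id` (the [ta()] string id), `trait`, `age_months`, `mean`,
#'   `sd` (sd may be 0 for a degenerate, noise-free variable).
#' @param corr Correlation matrix over `vars$id` (dimnames must match).
#'   Symmetric with unit diagonal; slightly indefinite matrices are
#'   repaired by eigenvalue clipping (see [repair_correlation()]).
#' @param link Slaughter link: `list(markers = <ids>, targets =
#'   list(<trait> = list(mean, slopes, sd)))` where `slopes` are the
#'   *univariate* population regression slopes of the target on each
#'   marker and `sd` is the total standard deviation of the target.  The
#'   generator solves for the multivariate coefficients that imply
#'   exactly those univariate slopes given the marker covariances.
#'   `NULL` produces a herd without slaughter records.
#' @param composition Fractions used to derive the remaining carcass
#'   components (bone and tendon as fractions of pulp, internal fat as a
#'   fraction of slaughter mass) plus the coefficient of variation of
#'   their multiplicative noise.  Chilled carcass mass is computed as
#'   pulp + bone + tendon, so the composition bound holds by
#'   construction.
#' @param groups Data frame with columns `sire_line`, `bloodline`,
#'   `prop` and optionally `mean_scale` (multiplier on all trait and
#'   target means; default 1, i.e. no group contrast).
#' @param provenance Free-form metadata list.
#' @return An object of class `"generator_config"`.
#' @seealso [default_herd_config()], [generate_herd()]
#' @export
generator_config <- function(n_animals, seed = NULL, vars, corr,
                             link = NULL,
                             composition = list(bone_frac = 0.244,
                                                tendon_frac = 0.0385,
                                                fat_frac = 0.05,
                                                cv = 0.02),
                             groups = NULL, provenance = list()) {
  stopifnot(n_animals >= 1, is.data.frame(vars),
            all(c("id", "trait", "age_months", "mean", "sd") %in%
                  names(vars)))
  if (any(vars$sd < 0)) stop("trait sds must be >= 0", call. = FALSE)
  if (any(vars$mean <= 0)) stop("trait means must be > 0", call. = FALSE)
  corr <- as.matrix(corr)
  if (is.null(dimnames(corr))) dimnames(corr) <- list(vars$id, vars$id)
  if (!identical(sort(colnames(corr)), sort(vars$id))) {
    stop("corr dimnames must match vars$id", call. = FALSE)
  }
  corr <- repair_correlation(corr[vars$id, vars$id])
  if (is.null(groups)) {
    groups <- data.frame(sire_line = "unspecified",
                         bloodline = "unspecified",
                         prop = 1, mean_scale = 1,
                         stringsAsFactors = FALSE)
  }
  if (is.null(groups$mean_scale)) groups$mean_scale <- 1
  groups$prop <- groups$prop / sum(groups$prop)
  if (!is.null(link)) {
    stopifnot(all(link$markers %in% vars$id))
    for (t in names(link$targets)) {
      tg <- link$targets[[t]]
      stopifnot(t %in% slaughter_traits(), tg$mean > 0, tg$sd >= 0,
                length(tg$slopes) == length(link$markers))
    }
  }
  structure(list(n_animals = as.integer(n_animals), seed = seed,
                 vars = vars, corr = corr, link = link,
                 composition = composition, groups = groups,
                 provenance = provenance),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic herd generator config:", x$n_animals, "animals,",
      nrow(x$vars), "longitudinal variables,",
      if (is.null(x$link)) "no slaughter link"
      else paste(length(x$link$targets), "linked slaughter targets"),
      "\n")
  invisible(x)
}

#' Repair a nearly positive-semidefinite correlation matrix
#'
#' Hand-specified, range-based correlation targets are often slightly
#' indefinite.  Negative eigenvalues no smaller than `-tol` are clipped
#' to zero and the matrix is re-normalized to unit diagonal; anything
#' more indefinite is rejected, naming the offending eigenvalue.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param tol Repair tolerance on the most negative eigenvalue.
#' @return A positive-semidefinite correlation matrix.
#' @export
repair_correlation <- function(R, tol = 1e-6) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) {
    stop("correlation matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > 1e-8) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lo <- min(e$values)
  if (lo < -tol) {
    stop(sprintf(paste0("correlation target is not positive semidefinite ",
                        "(eigenvalue %.3g below repair tolerance %g)"),
                 lo, tol), call. = FALSE)
  }
  if (lo < 0) {
    v <- pmax(e$values, 0)
    B <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(B))
    B <- B / tcrossprod(d)
    diag(B) <- 1
    dimnames(B) <- dimnames(R)
    return(B)
  }
  R
}

# saturating growth curve used to fill in intermediate-age means
growth_interp <- function(age, at_birth, at_18) {
  f <- (1 - exp(-age / 7.5)) / (1 - exp(-18 / 7.5))
  at_birth + (at_18 - at_birth) * f
}

#' The default herd configuration
#'
#' Returns a [generator_config()] whose moments match the anchor values
#' of the forecast machinery: dam live weight 512 kg, calf live weight
#' at birth 26 kg, withers height at birth 70 cm, pre-slaughter weight
#' 425.7 kg, slaughter weight 237.3 kg, pulp weight 175.2 kg, and whose
#' univariate marker-to-target slopes equal the canonical regression
#' coefficients (e.g. 11.3 kg pre-slaughter weight per kg of birth
#' weight, 5.1 kg per cm of withers height, 1.3 kg per kg of dam
#' weight).
#'
#' The longitudinal correlation structure is a proper factor model —
#' a shared size factor, an age factor with geometrically decaying
#' correlation across the seven measurement ages, and a trait factor —
#' chosen so that every implied correlation lies inside the canonical
#' published ranges: 0.7–0.9 between live weights at different ages
#' (exactly 0.90 for adjacent ages), 0.85 between body measurements at
#' the same age, and 0.40 between dam live weight and every offspring
#' trait.  Being model-implied, the matrix is positive definite by
#' construction.  Marker and target dispersions are back-derived from
#' the canonical regression coefficients and correlation ranges
#' (sigma = 19.3 kg dam weight, 5.0 kg birth weight, 9.85 cm withers
#' height at birth; 62.8 / 33.3 / 26.1 kg for the three targets).
#' Intermediate-age means are realistic growth-curve placeholders, not
#' published values.
#'
#' @param n_animals Number of animals (default 200, a typical single
#'   farm group).
#' @param seed Optional seed.
#' @return A `"generator_config"`.
#' @export
default_herd_config <- function(n_animals = 200, seed = NULL) {
  ages <- herd_ages()
  lw_means <- c(26, 105, 170, 235, 300, 365, 425.7)
  lw_sds <- 5 + (62.8 - 5) * (lw_means - 26) / (425.7 - 26)
  # (birth mean, 18-month mean, sd at birth); sd scales with the mean
  meas <- list(
    height_withers_cm = c(70, 127, 9.85),
    height_sacrum_cm = c(75, 132, 6.0),
    oblique_trunk_length_cm = c(60, 155, 4.8),
    chest_depth_cm = c(28, 70, 2.2),
    chest_width_cm = c(18, 45, 1.4),
    width_makloks_cm = c(20, 50, 1.6),
    chest_girth_cm = c(78, 190, 6.2),
    butt_half_girth_cm = c(30, 105, 2.4),
    pastern_girth_cm = c(11, 21, 0.9)
  )
  vars <- data.frame(trait = "live_weight_kg", age_months = ages,
                     mean = lw_means, sd = lw_sds,
                     stringsAsFactors = FALSE)
  for (tr in names(meas)) {
    m <- growth_interp(ages, meas[[tr]][1], meas[[tr]][2])
    vars <- rbind(vars, data.frame(
      trait = tr, age_months = ages, mean = m,
      sd = meas[[tr]][3] * m / meas[[tr]][1], stringsAsFactors = FALSE))
  }
  vars <- rbind(vars, data.frame(trait = "dam_live_weight_kg",
                                 age_months = NA_integer_,
                                 mean = 512, sd = 19.3,
                                 stringsAsFactors = FALSE))
  vars$id <- ifelse(is.na(vars$age_months), vars$trait,
                    paste0(vars$trait, "@", vars$age_months))

  # factor-model implied correlations: var = a2 (size) + b2 (age factor,
  # AR decay 0.75 per age step) + g2 (trait factor) + d2 (noise)
  a2 <- 0.70; b2 <- 0.15; g2 <- 0.0875
  rho <- 0.75
  k <- nrow(vars)
  R <- diag(k)
  dimnames(R) <- list(vars$id, vars$id)
  idx <- match(vars$age_months, ages)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (is.na(idx[i]) || is.na(idx[j])) {
        r <- 0.40  # dam live weight vs any offspring trait
      } else {
        r <- a2 + b2 * rho^abs(idx[i] - idx[j]) +
          if (vars$trait[i] == vars$trait[j]) g2 else 0
      }
      R[i, j] <- R[j, i] <- r
    }
  }

  link <- list(
    markers = c("dam_live_weight_kg", "live_weight_kg@0",
                "height_withers_cm@0"),
    targets = list(
      pre_slaughter_mass_kg = list(mean = 425.7,
                                   slopes = c(1.3, 11.3, 5.1), sd = 62.8),
      slaughter_mass_kg = list(mean = 237.3,
                               slopes = c(0.8, 6.0, 2.8), sd = 33.3),
      pulp_mass_kg = list(mean = 175.2,
                          slopes = c(0.6, 4.7, 1.9), sd = 26.1)))

  groups <- data.frame(
    sire_line = c("Franc 10736366", "Vis Idiala 933122",
                  "Siling Trijun 252803"),
    bloodline = c("Black-and-White", "1/2 Holstein", "1/4 Holstein"),
    prop = c(1, 1, 1) / 3, mean_scale = 1, stringsAsFactors = FALSE)

  generator_config(n_animals = n_animals, seed = seed, vars = vars,
                   corr = R, link = link, groups = groups,
                   provenance = list(farm = "synthetic", seed = seed))
}

# multivariate link coefficients implying the configured univariate
# slopes, given the marker covariance matrix
solve_link <- function(target, marker_sds, marker_corr) {
  Sm <- diag(marker_sds) %*% marker_corr %*% diag(marker_sds)
  g <- target$slopes * marker_sds^2
  coef <- solve(Sm, g)
  explained <- sum(coef * g)
  resid_var <- target$sd^2 - explained
  if (resid_var < -1e-8) {
    stop(sprintf(paste0("slaughter link for target with sd %.3g is ",
                        "over-determined: implied explained sd %.3g ",
                        "exceeds the total"),
                 target$sd, sqrt(explained)), call. = FALSE)
  }
  list(coef = coef, resid_sd = sqrt(max(resid_var, 0)))
}

#' Generate a synthetic herd
#'
#' Draws `n_animals` complete longitudinal records from the configured
#' joint distribution and, when a slaughter link is configured, a full
#' set of slaughter indices per animal.  Deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A [herd_dataset()].
#' @export
generate_herd <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_animals
  vars <- config$vars
  k <- nrow(vars)

  # symmetric square root handles exactly-singular repaired matrices
  e <- eigen(config$corr, symmetric = TRUE)
  A <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  Z <- matrix(stats::rnorm(n * k), n, k) %*% A
  Z <- pmax(Z, -3)  # keep masses and measurements positive
  colnames(Z) <- vars$id

  grp <- sample.int(nrow(config$groups), n, replace = TRUE,
                    prob = config$groups$prop)
  scale_g <- config$groups$mean_scale[grp]
  X <- sweep(Z, 2, vars$sd, `*`)
  X <- X + outer(scale_g, vars$mean)
  colnames(X) <- vars$id

  ids <- sprintf("A%05d", seq_len(n))
  dam <- if ("dam_live_weight_kg" %in% vars$id) {
    X[, "dam_live_weight_kg"]
  } else {
    rep(NA_real_, n)
  }
  animals <- data.frame(
    animal_id = ids, sex = "M",
    sire_line = config$groups$sire_line[grp],
    bloodline = config$groups$bloodline[grp],
    dam_live_weight_kg = dam, stringsAsFactors = FALSE)

  long <- vars[vars$id != "dam_live_weight_kg", ]
  observations <- data.frame(
    animal_id = rep(ids, times = nrow(long)),
    trait = rep(long$trait, each = n),
    age_months = rep(long$age_months, each = n),
    value = as.vector(X[, long$id]), stringsAsFactors = FALSE)

  slaughter <- NULL
  if (!is.null(config$link)) {
    lk <- config$link
    M <- X[, lk$markers, drop = FALSE]
    msd <- vars$sd[match(lk$markers, vars$id)]
    mmu <- vars$mean[match(lk$markers, vars$id)]
    mcorr <- config$corr[lk$markers, lk$markers]
    out <- list(animal_id = ids)
    centred <- M - outer(scale_g, mmu)
    for (t in names(lk$targets)) {
      tg <- lk$targets[[t]]
      sl <- solve_link(tg, msd, mcorr)
      y <- tg$mean * scale_g + centred %*% sl$coef +
        stats::rnorm(n, 0, sl$resid_sd)
      out[[t]] <- pmax(as.vector(y), tg$mean * 0.05)
    }
    cp <- config$composition
    noise <- function() 1 + stats::rnorm(n, 0, cp$cv)
    pulp <- out$pulp_mass_kg
    slau <- out$slaughter_mass_kg
    bone <- cp$bone_frac * pulp * noise()
    tendon <- cp$tendon_frac * pulp * noise()
    fat <- cp$fat_frac * slau * noise()
    out$bone_mass_kg <- bone
    out$tendon_mass_kg <- tendon
    out$chilled_carcass_mass_kg <- pulp + bone + tendon
    out$internal_fat_mass_kg <- fat
    out$paired_carcass_mass_kg <- slau - fat
    out$half_carcass_mass_kg <- out$paired_carcass_mass_kg / 2
    slaughter <- as.data.frame(out, stringsAsFactors = FALSE)
    slaughter <- slaughter[, c("animal_id", slaughter_traits())]
  }

  herd_dataset(animals, observations, slaughter,
               provenance = c(config$provenance,
                              list(n_animals = n, generator = "herdcast")))
}

#' Generate dam-offspring pairs with known heritability
#'
#' Simulates pairs whose phenotypic correlation is exactly
#' `h2_true / 2`, the parent-offspring resemblance implied by an
#' additive trait of heritability `h2_true`.  The dam phenotype is
#' stored in `dam_live_weight_kg`, the instrument the heritability
#' estimator reads, and the offspring phenotype as a trait observation.
#' Used for parameter-recovery testing of [estimate_heritability()].
#'
#' @param h2_true True heritability, in `[0, 1]`.
#' @param n_pairs Number of dam-offspring pairs.
#' @param trait,age Offspring trait and age (default: live weight at
#'   birth).
#' @param config Config supplying means and dispersions (default
#'   [default_herd_config()]).
#' @param seed Optional seed.
#' @return A [herd_dataset()] of `n_pairs` animals.
#' @export
generate_parent_offspring <- function(h2_true, n_pairs = 200,
                                      trait = "live_weight_kg", age = 0,
                                      config = default_herd_config(),
                                      seed = NULL) {
  if (!is.numeric(h2_true) || length(h2_true) != 1 ||
      h2_true < 0 || h2_true > 1) {
    stop("h2_true must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  off <- config$vars[config$vars$trait == trait &
                       config$vars$age_months %in% age, ]
  if (nrow(off) != 1) stop("trait/age not in config", call. = FALSE)
  dam_row <- config$vars[config$vars$trait == "dam_live_weight_kg", ]
  dam_mean <- if (trait == "live_weight_kg" && nrow(dam_row)) {
    dam_row$mean
  } else {
    off$mean
  }
  r <- h2_true / 2
  z1 <- stats::rnorm(n_pairs)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n_pairs)
  z1 <- pmax(z1, -3); z2 <- pmax(z2, -3)
  dam <- dam_mean + off$sd * z1        # dam phenotype, trait-scale spread
  offv <- off$mean + off$sd * z2
  ids <- sprintf("P%05d", seq_len(n_pairs))
  herd_dataset(
    animals = data.frame(animal_id = ids, sex = "M",
                         sire_line = "unspecified",
                         bloodline = "unspecified",
                         dam_live_weight_kg = dam,
                         stringsAsFactors = FALSE),
    observations = data.frame(animal_id = ids, trait = trait,
                              age_months = as.integer(age), value = offv,
                              stringsAsFactors = FALSE),
    provenance = list(generator = "parent_offspring", h2_true = h2_true))
}
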