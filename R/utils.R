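#' Round half away from zero
#'
#' Zootechnical tables are conventionally rendered with "commercial"
#' rounding (half rounds up), not the IEEE round-half-even rule used by
#' [round()].  All table cells and accuracy percentages printed by this
#' package go through this function; full precision is always kept
#' internally.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(89.83, 0)  # 90, where round() would also give 90
#' round_half_up(0.5, 0)    # 1, where round() gives 0
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Trait/age pair
#'
#' A light-weight identifier for a measured quantity: a trait name plus
#' the age (in months) at which it was recorded.  Age 0 means "at
#' birth".  Dam live weight and the slaughter indices are per-animal
#' scalars, so their age is `NA`.
#'
#' @param trait Trait name; one of [longitudinal_traits()],
#'   `"dam_live_weight_kg"`, or one of [slaughter_traits()].
#' @param age Age in months (`0, 3, 6, 9, 12, 15, 18`), or `NA` for
#'   ageless traits.
#' @return An object of class `"trait_age"`.
#' @examples
#' ta("live_weight_kg", 0)      # calf live weight at birth
#' ta("dam_live_weight_kg")     # live weight of the mother
#' @export
ta <- function(trait, age = NA_integer_) {
  trait <- as.character(trait)
  stopifnot(length(trait) == 1L, length(age) == 1L)
  ageless <- trait == "dam_live_weight_kg" || trait %in% slaughter_traits()
  if (ageless) {
    age <- NA_integer_
  } else {
    if (!trait %in% longitudinal_traits()) {
      stop("unknown trait: ", trait, call. = FALSE)
    }
    age <- as.integer(age)
    if (is.na(age) || !age %in% herd_ages()) {
      stop("age must be one of ", paste(herd_ages(), collapse = ", "),
           " for trait ", trait, call. = FALSE)
    }
  }
  structure(list(trait = trait, age = age), class = "trait_age")
}

#' @export
print.trait_age <- function(x, ...) {
  cat(ta_id(x), "\n")
  invisible(x)
}

# canonical string id for a trait/age pair ("trait@age" or bare name)
ta_id <- function(x) {
  if (is.na(x$age)) x$trait else paste0(x$trait, "@", x$age)
}

# parse "trait@age" back into a trait_age
ta_parse <- function(id) {
  if (inherits(id, "trait_age")) return(id)
  parts <- strsplit(id, "@", fixed = TRUE)[[1]]
  if (length(parts) == 2L) ta(parts[1], as.integer(parts[2])) else ta(parts[1])
}

# human-readable label used in printed tables
ta_label <- function(x) {
  lab <- c(
    live_weight_kg = "live weight, kg",
    height_withers_cm = "height at the withers, cm",
    height_sacrum_cm = "height at the sacrum, cm",
    oblique_trunk_length_cm = "oblique trunk length, cm",
    chest_depth_cm = "chest depth, cm",
    chest_width_cm = "chest width, cm",
    width_makloks_cm = "width in makloks, cm",
    chest_girth_cm = "chest girth, cm",
    butt_half_girth_cm = "butt half-girth, cm",
    pastern_girth_cm = "pastern girth, cm",
    dam_live_weight_kg = "live weight of the mother, kg",
    pre_slaughter_mass_kg = "pre-slaughter weight, kg",
    paired_carcass_mass_kg = "paired carcass weight, kg",
    internal_fat_mass_kg = "internal fat weight, kg",
    slaughter_mass_kg = "slaughter weight, kg",
    chilled_carcass_mass_kg = "chilled carcass weight, kg",
    pulp_mass_kg = "pulp weight, kg",
    bone_mass_kg = "bone weight, kg",
    tendon_mass_kg = "tendon weight, kg",
    half_carcass_mass_kg = "half-carcass weight, kg"
  )[[x$trait]]
  if (is.na(x$age)) lab
  else if (x$age == 0L) paste(lab, "at birth")
  else paste0(lab, " at ", x$age, " months")
}

#' Trait vocabularies
#'
#' The longitudinal traits are recorded at the standard ontogenesis ages
#' (birth plus 3-month steps to 18 months); the slaughter traits are the
#' nine post-slaughter masses recorded once per animal.
#'
#' @return Character vector of trait names (or integer ages for
#'   `herd_ages()`).
#' @export
longitudinal_traits <- function() {
  c("live_weight_kg", "height_withers_cm", "height_sacrum_cm",
    "oblique_trunk_length_cm", "chest_depth_cm", "chest_width_cm",
    "width_makloks_cm", "chest_girth_cm", "butt_half_girth_cm",
    "pastern_girth_cm")
}

#' @rdname longitudinal_traits
#' @export
slaughter_traits <- function() {
  c("pre_slaughter_mass_kg", "paired_carcass_mass_kg",
    "internal_fat_mass_kg", "slaughter_mass_kg",
    "chilled_carcass_mass_kg", "pulp_mass_kg", "bone_mass_kg",
    "tendon_mass_kg", "half_carcass_mass_kg")
}

#' @rdname longitudinal_traits
#' @export
herd_ages <- function() c(0L, 3L, 6L, 9L, 12L, 15L, 18L)

#' The default birth-time marker set
#'
#' Dam live weight, calf live weight at birth and calf height at the
#' withers at birth: the three traits available on day one of an
#' animal's life that carry usable information about its slaughter-age
#' productivity.
#'
#' @return List of [ta()] pairs.
#' @export
default_markers <- function() {
  list(ta("dam_live_weight_kg"),
       ta("live_weight_kg", 0),
       ta("height_withers_cm", 0))
}

#' Default forecast targets
#'
#' The three slaughter indices with the most practical value for herd
#' planning: pre-slaughter weight, slaughter weight and pulp weight.
#'
#' @return Character vector of slaughter trait names.
#' @export
default_targets <- function() {
  c("pre_slaughter_mass_kg", "slaughter_mass_kg", "pulp_mass_kg")
}
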