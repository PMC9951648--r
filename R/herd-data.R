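#' Assemble a herd dataset
#'
#' A `herd_dataset` bundles the three record types collected on a farm:
#' one row per animal (identity, pedigree grouping, dam live weight),
#' the longitudinal trait observations (live weight and body
#' measurements at birth and at 3, 6, 9, 12, 15, 18 months), and the
#' optional post-slaughter masses.
#'
#' @param animals Data frame with columns `animal_id`, `sex`,
#'   `sire_line`, `bloodline`, `dam_live_weight_kg`.
#' @param observations Data frame with columns `animal_id`, `trait`,
#'   `age_months`, `value`.
#' @param slaughter Optional data frame with column `animal_id` plus the
#'   nine [slaughter_traits()] columns.  `NULL` means no slaughter data.
#' @param provenance Free-form list of metadata (farm label, generator
#'   seed, ...).
#' @return A validated object of class `"herd_dataset"`.
#' @seealso [read_herd()], [write_herd()], [subset_by_group()]
#' @export
herd_dataset <- function(animals, observations,
                         slaughter = NULL, provenance = list()) {
  if (is.null(slaughter)) {
    slaughter <- empty_slaughter()
  }
  animals <- as.data.frame(animals, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)
  slaughter <- as.data.frame(slaughter, stringsAsFactors = FALSE)
  x <- structure(
    list(animals = animals, observations = observations,
         slaughter = slaughter, provenance = provenance),
    class = "herd_dataset")
  validate_herd(x)
}

empty_slaughter <- function() {
  cols <- c("animal_id", slaughter_traits())
  out <- as.data.frame(stats::setNames(
    c(list(character(0)), rep(list(numeric(0)), length(slaughter_traits()))),
    cols), stringsAsFactors = FALSE)
  out
}

animals_cols <- function() {
  c("animal_id", "sex", "sire_line", "bloodline", "dam_live_weight_kg")
}

#' Validate a herd dataset
#'
#' Checks the structural invariants: required columns present, unique
#' animal ids, unique (animal, trait, age) observations, positive
#' values, every observation and slaughter record resolving to a known
#' animal, and the carcass composition bound
#' pulp + bone + tendon <= chilled carcass (1% relative tolerance, to
#' absorb rounding in recorded data).
#'
#' @param x A `herd_dataset`.
#' @param composition_tol Relative tolerance for the composition bound.
#' @return `x`, invisibly classed, if valid; otherwise an error.
#' @export
validate_herd <- function(x, composition_tol = 0.01) {
  stopifnot(inherits(x, "herd_dataset"))
  need <- setdiff(animals_cols(), names(x$animals))
  if (length(need)) {
    stop("animals table is missing column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  need <- setdiff(c("animal_id", "trait", "age_months", "value"),
                  names(x$observations))
  if (length(need)) {
    stop("observations table is missing column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  need <- setdiff(c("animal_id", slaughter_traits()), names(x$slaughter))
  if (length(need)) {
    stop("slaughter table is missing column(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ids <- x$animals$animal_id
  if (anyDuplicated(ids)) {
    stop("duplicated animal_id in animals table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  dlw <- x$animals$dam_live_weight_kg
  if (any(!is.na(dlw) & dlw <= 0)) {
    stop("dam_live_weight_kg must be positive where present", call. = FALSE)
  }
  obs <- x$observations
  if (nrow(obs)) {
    bad <- setdiff(unique(obs$animal_id), ids)
    if (length(bad)) {
      stop("observations reference unknown animal_id: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(!obs$trait %in% longitudinal_traits())) {
      stop("unknown trait in observations: ",
           paste(setdiff(unique(obs$trait), longitudinal_traits()),
                 collapse = ", "), call. = FALSE)
    }
    if (any(!obs$age_months %in% herd_ages())) {
      stop("age_months must be one of ",
           paste(herd_ages(), collapse = ", "), call. = FALSE)
    }
    if (any(!is.na(obs$value) & obs$value <= 0)) {
      stop("observation values must be positive", call. = FALSE)
    }
    key <- paste(obs$animal_id, obs$trait, obs$age_months)
    if (anyDuplicated(key)) {
      stop("duplicated (animal_id, trait, age_months) in observations: ",
           paste(unique(key[duplicated(key)]), collapse = "; "),
           call. = FALSE)
    }
  }
  sl <- x$slaughter
  if (nrow(sl)) {
    bad <- setdiff(unique(sl$animal_id), ids)
    if (length(bad)) {
      stop("slaughter records reference unknown animal_id: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    mass <- as.matrix(sl[, slaughter_traits()])
    if (any(!is.na(mass) & mass <= 0)) {
      stop("slaughter masses must be positive", call. = FALSE)
    }
    comp <- sl$pulp_mass_kg + sl$bone_mass_kg + sl$tendon_mass_kg
    over <- !is.na(comp) & !is.na(sl$chilled_carcass_mass_kg) &
      comp > sl$chilled_carcass_mass_kg * (1 + composition_tol)
    if (any(over)) {
      stop("pulp + bone + tendon exceeds chilled carcass mass for: ",
           paste(sl$animal_id[over], collapse = ", "), call. = FALSE)
    }
    parts <- setdiff(slaughter_traits(), "pre_slaughter_mass_kg")
    over <- rowSums(sl[, parts] >=
                      sl$pre_slaughter_mass_kg * (1 + composition_tol),
                    na.rm = TRUE) > 0
    if (any(over)) {
      stop("component mass >= pre-slaughter mass for: ",
           paste(sl$animal_id[over], collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.herd_dataset <- function(x, ...) {
  cat("Herd dataset:", nrow(x$animals), "animals,",
      nrow(x$observations), "trait observations,",
      nrow(x$slaughter), "slaughter records\n")
  if (length(x$provenance)) {
    cat("  provenance:",
        paste(names(x$provenance), unlist(lapply(x$provenance, format)),
              sep = " = ", collapse = "; "), "\n")
  }
  grp <- table(x$animals$sire_line)
  if (length(grp) > 1L) {
    cat("  sire lines:",
        paste(names(grp), grp, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a herd dataset from delimited files
#'
#' Expects the three-file layout written by [write_herd()]:
#' `animals.csv`, `observations.csv` and (optionally) `slaughter.csv`
#' in one directory, each with a header row.  Empty cells are read as
#' missing values, never as zero.
#'
#' @param dir Directory containing the files.
#' @param delim Field delimiter: `","` (default), `"\t"` or `";"`.
#' @return A validated [herd_dataset()].
#' @export
read_herd <- function(dir, delim = ",") {
  paths <- file.path(dir, c("animals.csv", "observations.csv",
                            "slaughter.csv"))
  if (!file.exists(paths[1])) stop("file not found: ", paths[1], call. = FALSE)
  if (!file.exists(paths[2])) stop("file not found: ", paths[2], call. = FALSE)
  animals <- read_herd_table(paths[1], delim, animals_cols(),
                             numeric_cols = "dam_live_weight_kg")
  observations <- read_herd_table(paths[2], delim,
                                  c("animal_id", "trait", "age_months",
                                    "value"),
                                  numeric_cols = c("age_months", "value"))
  observations$age_months <- as.integer(observations$age_months)
  slaughter <- NULL
  prov <- list(source = normalizePath(dir))
  if (file.exists(paths[3])) {
    slaughter <- read_herd_table(paths[3], delim,
                                 c("animal_id", slaughter_traits()),
                                 numeric_cols = slaughter_traits())
  }
  herd_dataset(animals, observations, slaughter, provenance = prov)
}

# read one table, enforcing schema and reporting row-level parse errors
read_herd_table <- function(path, delim, required, numeric_cols) {
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "", quote = "\"",
                           comment.char = "")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("file ", basename(path), " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in numeric_cols) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(val))
    if (length(bad)) {
      # +1 for the header line
      stop("file ", basename(path), ", column ", col,
           ": non-numeric value ", dQuote(raw[[col]][bad[1]]),
           " at line ", bad[1] + 1L, call. = FALSE)
    }
    raw[[col]] <- val
  }
  raw
}

#' Write a herd dataset to delimited files
#'
#' Writes `animals.csv`, `observations.csv` and `slaughter.csv` into
#' `dir`.  Numeric values are rendered to `digits` decimal places
#' (round half up, default 1, the convention of zootechnical tables);
#' missing values become empty cells.  An empty slaughter collection
#' produces a header-only file so that the layout is always complete.
#'
#' @param x A `herd_dataset`.
#' @param dir Output directory; created if needed.
#' @param delim Field delimiter.
#' @param digits Decimal places for numeric rendering.
#' @return Invisibly, the paths written.
#' @export
write_herd <- function(x, dir, delim = ",", digits = 1) {
  validate_herd(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) {
    stop("directory not writable: ", dir, call. = FALSE)
  }
  paths <- file.path(dir, c("animals.csv", "observations.csv",
                            "slaughter.csv"))
  write_herd_table(x$animals, paths[1], delim, digits)
  write_herd_table(x$observations, paths[2], delim, digits)
  write_herd_table(x$slaughter, paths[3], delim, digits)
  invisible(paths)
}

write_herd_table <- function(df, path, delim, digits) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      v <- round_half_up(out[[col]], digits)
      # drop trailing ".0" for integral values, matching table style
      s <- ifelse(is.na(v), NA_character_,
                  sub("\\.?0+$", "", formatC(v, format = "f",
                                             digits = digits)))
      out[[col]] <- s
    }
  }
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Subset a herd by pedigree group
#'
#' Restricts a dataset to the animals of one sire line or one bloodline
#' (with their observations and slaughter records), mirroring the
#' per-group columns of zootechnical correlation tables.  Subsetting by
#' every level of a grouping partitions the herd.
#'
#' @param x A `herd_dataset`.
#' @param grouping `"sire_line"`, `"bloodline"` or `"all"`.
#' @param level Group label; required unless `grouping = "all"`.
#' @return A `herd_dataset` containing only the selected animals.
#' @export
subset_by_group <- function(x, grouping = c("all", "sire_line", "bloodline"),
                            level = NULL) {
  stopifnot(inherits(x, "herd_dataset"))
  grouping <- match.arg(grouping)
  if (grouping == "all") return(x)
  if (is.null(level)) stop("level is required when grouping != 'all'",
                           call. = FALSE)
  pool <- x$animals[[grouping]]
  if (!level %in% pool) {
    stop("unknown ", grouping, " level: ", level, call. = FALSE)
  }
  keep <- x$animals$animal_id[pool == level]
  herd_dataset(
    animals = x$animals[x$animals$animal_id %in% keep, , drop = FALSE],
    observations = x$observations[
      x$observations$animal_id %in% keep, , drop = FALSE],
    slaughter = x$slaughter[x$slaughter$animal_id %in% keep, , drop = FALSE],
    provenance = c(x$provenance, list(subset = paste(grouping, level))))
}

#' Extract the per-animal values of one trait
#'
#' Returns a named numeric vector (names are animal ids) for a
#' [ta()] pair: dam live weight comes from the animals table, slaughter
#' indices from the slaughter table, longitudinal traits from the
#' observations at the requested age.
#'
#' @param x A `herd_dataset`.
#' @param pair A [ta()] trait/age pair (or its string id).
#' @return Named numeric vector; animals without a value are absent.
#' @export
herd_values <- function(x, pair) {
  stopifnot(inherits(x, "herd_dataset"))
  pair <- ta_parse(pair)
  if (pair$trait == "dam_live_weight_kg") {
    v <- stats::setNames(x$animals$dam_live_weight_kg, x$animals$animal_id)
  } else if (pair$trait %in% slaughter_traits()) {
    v <- stats::setNames(x$slaughter[[pair$trait]], x$slaughter$animal_id)
  } else {
    obs <- x$observations
    sel <- obs$trait == pair$trait & obs$age_months == pair$age
    v <- stats::setNames(obs$value[sel], obs$animal_id[sel])
  }
  v[!is.na(v)]
}
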