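#' Configure a pipeline run
#'
#' Bundles everything a full prognosis run needs: the input herd
#' (either a directory of delimited files or a generator config), the
#' analysis settings of each stage, the output directory and the seed.
#'
#' @param input Directory containing `animals.csv` /
#'   `observations.csv` / `slaughter.csv`, or `NULL` when `generator`
#'   is given.
#' @param generator A [generator_config()] to simulate the herd
#'   instead of reading one.
#' @param out_dir Output directory for the stage artefacts.
#' @param seed Integer seed; required when a generator is used.
#' @param grouping Grouping for the correlation tables.
#' @param alpha Reliability level.
#' @param markers,targets Candidate markers and forecast targets.
#' @param screen_threshold,require_reliable Marker screen settings.
#' @param half_width,step Forecast-table grid.
#' @param top_fraction Selection rule for the selection-effect stage.
#' @param delim Delimiter for all written tables.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, generator = NULL,
                            out_dir = "herdcast_out", seed = NULL,
                            grouping = "all", alpha = 0.05,
                            markers = default_markers(),
                            targets = default_targets(),
                            screen_threshold = 0.3,
                            require_reliable = TRUE,
                            half_width = 6, step = 1,
                            top_fraction = 0.2, delim = ",") {
  if (is.null(input) && is.null(generator)) {
    stop("either input or generator must be given", call. = FALSE)
  }
  if (!is.null(generator) && is.null(seed) && is.null(generator$seed)) {
    stop("a seed is required when the herd is generated", call. = FALSE)
  }
  structure(list(input = input, generator = generator,
                 out_dir = out_dir, seed = seed, grouping = grouping,
                 alpha = alpha, markers = lapply(markers, ta_parse),
                 targets = targets,
                 screen_threshold = screen_threshold,
                 require_reliable = require_reliable,
                 half_width = half_width, step = step,
                 top_fraction = top_fraction, delim = delim),
            class = "pipeline_config")
}

#' Read a pipeline config from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `markers`
#' are given as string ids (e.g. `live_weight_kg@0`).  A `generator`
#' block with `n_animals` (and optional `seed`) requests the default
#' synthetic herd at that size.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(y$generator)) {
    gen <- default_herd_config(
      n_animals = y$generator$n_animals,
      seed = if (!is.null(y$generator$seed)) y$generator$seed else y$seed)
  }
  args <- y[setdiff(names(y), "generator")]
  if (!is.null(args$markers)) {
    args$markers <- lapply(args$markers, ta_parse)
  }
  do.call(pipeline_config, c(args, list(generator = gen)))
}

write_stage <- function(df, dir, name, delim) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "")
  list(file = name, rows = nrow(df))
}

#' Run the full prognosis pipeline
#'
#' Executes the staged workflow in order — simulate/load, descriptive
#' biometry, correlation tables, marker screening, regression
#' coefficients, forecast tables, forecasting and approbation, and the
#' selection-effect report — writing each stage's artefact as a
#' delimited file plus a JSON run manifest.  A rerun with the same
#' config and seed reproduces the outputs exactly.  When the herd has
#' no slaughter records the forecasting and selection stages are
#' skipped with a warning.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `"run_manifest"`: per-stage file lists
#'   and row counts, the config snapshot and the package version.
#'   The manifest is also written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  stages <- list()

  # stage 0: obtain the herd
  if (!is.null(config$generator)) {
    gen <- config$generator
    if (!is.null(config$seed)) gen$seed <- config$seed
    herd <- generate_herd(gen)
    herd_dir <- file.path(config$out_dir, "herd")
    write_herd(herd, herd_dir, delim = config$delim)
    stages$simulate <- list(file = "herd/", rows = nrow(herd$animals))
  } else {
    herd <- read_herd(config$input, delim = config$delim)
    stages$load <- list(file = config$input, rows = nrow(herd$animals))
  }
  has_slaughter <- nrow(herd$slaughter) > 0

  # stage 1: descriptive biometry
  present <- unique(herd$observations[, c("trait", "age_months")])
  desc_rows <- lapply(seq_len(nrow(present)), function(i) {
    d <- describe(herd, present$trait[i], present$age_months[i])
    data.frame(trait = d$trait, age_months = d$age_months, n = d$n,
               mean = d$mean, sem = d$sem, sd = d$sd,
               stringsAsFactors = FALSE)
  })
  if (any(!is.na(herd$animals$dam_live_weight_kg))) {
    d <- describe(herd, "dam_live_weight_kg")
    desc_rows <- c(desc_rows, list(
      data.frame(trait = d$trait, age_months = NA_integer_, n = d$n,
                 mean = d$mean, sem = d$sem, sd = d$sd,
                 stringsAsFactors = FALSE)))
  }
  if (has_slaughter) {
    for (t in slaughter_traits()) {
      d <- describe(herd, t)
      desc_rows <- c(desc_rows, list(
        data.frame(trait = d$trait, age_months = NA_integer_, n = d$n,
                   mean = d$mean, sem = d$sem, sd = d$sd,
                   stringsAsFactors = FALSE)))
    }
  }
  stages$describe <- write_stage(do.call(rbind, desc_rows),
                                 config$out_dir, "descriptives.csv",
                                 config$delim)

  # stage 2: correlation tables
  ct_ages <- correlation_table(herd, axis = "ages",
                               grouping = config$grouping,
                               alpha = config$alpha)
  stages$correlate <- write_stage(ct_ages, config$out_dir,
                                  "correlations_ages.csv", config$delim)
  if (length(setdiff(unique(present$trait), "live_weight_kg")) >= 2) {
    ct_meas <- correlation_table(herd, axis = "measurements",
                                 grouping = "all",
                                 alpha = config$alpha)
    stages$correlate_measurements <-
      write_stage(ct_meas, config$out_dir,
                  "correlations_measurements.csv", config$delim)
  }

  if (!has_slaughter) {
    warning("herd has no slaughter records: forecasting and selection ",
            "stages skipped", call. = FALSE)
    fit <- NULL
  } else {
    # stages 3-5: screen, coefficients, forecast tables
    mset <- screen_markers(herd, candidates = config$markers,
                           targets = config$targets,
                           threshold = config$screen_threshold,
                           require_reliable = config$require_reliable,
                           alpha = config$alpha)
    stages$screen <- write_stage(mset$screen, config$out_dir,
                                 "marker_screen.csv", config$delim)
    fit <- herdcast(herd,
                    markers = if (length(mset$markers)) mset$markers
                              else config$markers,
                    targets = config$targets, alpha = config$alpha,
                    screen = FALSE, half_width = config$half_width,
                    step = config$step)
    cf <- do.call(rbind, lapply(fit$coefficients, function(x)
      data.frame(marker = ta_id(x$marker), target = ta_id(x$target),
                 b = x$b, r = x$r_used, sd_target = x$sd_target,
                 sd_marker = x$sd_marker, stringsAsFactors = FALSE)))
    stages$coefficients <- write_stage(cf, config$out_dir,
                                       "coefficients.csv", config$delim)
    for (m in names(fit$tables)) {
      fname <- paste0("forecast_table_", gsub("@", "_at_", m), ".csv")
      stages[[paste0("table_", m)]] <-
        write_stage(format(fit$tables[[m]]), config$out_dir, fname,
                    config$delim)
    }

    # stage 6: per-animal forecasts and self-approbation
    fc <- predict(fit)
    fc_df <- data.frame(animal_id = rownames(fc), fc,
                        row.names = NULL, check.names = FALSE,
                        stringsAsFactors = FALSE)
    stages$forecast <- write_stage(fc_df, config$out_dir,
                                   "forecasts.csv", config$delim)
    acc <- approbate(test = herd, external_tables = fit$tables,
                     targets = config$targets, farm = "training herd")
    stages$evaluate <- write_stage(acc, config$out_dir,
                                   "accuracy.csv", config$delim)

    # stage 7: selection effect and propagation to slaughter indices
    h2 <- tryCatch(estimate_heritability(herd, alpha = config$alpha),
                   error = function(e) NULL)
    if (!is.null(h2)) {
      S <- selection_differential(herd, top_fraction =
                                    config$top_fraction)
      eff <- selection_effect(S, h2)
      sel_rows <- data.frame(
        target = "live_weight_kg@0", b = NA_real_,
        differential = S, h2 = h2$h2,
        effect = eff$effect_per_generation, stringsAsFactors = FALSE)
      lw18 <- describe(herd, "live_weight_kg", 18)
      for (t in config$targets) {
        cfb <- regression_coefficient(
          lw18, describe(herd, t),
          correlate(herd, ta("live_weight_kg", 18), ta(t),
                    config$alpha))
        S18 <- selection_differential(herd, "live_weight_kg", 18,
                                      top_fraction = config$top_fraction)
        eff18 <- selection_effect(S18, h2$h2)
        pe <- propagate_effect(eff18, cfb)
        sel_rows <- rbind(sel_rows, data.frame(
          target = t, b = pe$b, differential = S18, h2 = h2$h2,
          effect = pe$effect_target, stringsAsFactors = FALSE))
      }
      stages$selection <- write_stage(sel_rows, config$out_dir,
                                      "selection_effects.csv",
                                      config$delim)
    }
  }

  manifest <- structure(
    list(package = "herdcast",
         version = as.character(utils::packageVersion("herdcast")),
         timestamp = format(Sys.time(), tz = "UTC"),
         seed = config$seed,
         n_animals = nrow(herd$animals),
         stages = stages),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("herdcast pipeline run (", x$version, ", seed ",
      if (is.null(x$seed)) "none" else x$seed, ")\n", sep = "")
  cat("  herd:", x$n_animals, "animals\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-24s %s (%s rows)\n", s, x$stages[[s]]$file,
                x$stages[[s]]$rows))
  }
  invisible(x)
}
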