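test_that("regression coefficient follows b = r * sd_y / sd_x", {
  mk <- make_desc("live_weight_kg", 0L, 26, 5)
  tg <- make_desc("pre_slaughter_mass_kg", NA_integer_, 425.7, 62.8)
  b <- regression_coefficient(mk, tg,
                              make_cor(ta("live_weight_kg", 0),
                                       ta("pre_slaughter_mass_kg"), 0.9))
  expect_equal(round_half_up(b$b, 2), 11.3)

  b0 <- regression_coefficient(mk, tg,
                               make_cor(ta("live_weight_kg", 0),
                                        ta("pre_slaughter_mass_kg"), 0))
  expect_equal(b0$b, 0)

  tg1 <- make_desc("pre_slaughter_mass_kg", NA_integer_, 400, 5)
  b1 <- regression_coefficient(mk, tg1,
                               make_cor(ta("live_weight_kg", 0),
                                        ta("pre_slaughter_mass_kg"), 1))
  expect_equal(b1$b, 1)

  degen <- make_desc("live_weight_kg", 0L, 26, 0)
  expect_error(
    regression_coefficient(degen, tg,
                           make_cor(ta("live_weight_kg", 0),
                                    ta("pre_slaughter_mass_kg"), 0.5)),
    "degenerate")
  wrong <- make_cor(ta("live_weight_kg", 3),
                    ta("pre_slaughter_mass_kg"), 0.5)
  expect_error(regression_coefficient(mk, tg, wrong), "does not relate")
})

test_that("reciprocal slopes multiply to r squared and match least squares", {
  herd <- generate_herd(default_herd_config(400, seed = 23))
  mk <- describe(herd, "live_weight_kg", 0)
  tg <- describe(herd, "pre_slaughter_mass_kg")
  est <- correlate(herd, ta("live_weight_kg", 0),
                   ta("pre_slaughter_mass_kg"))
  b_yx <- regression_coefficient(mk, tg, est)
  b_xy <- regression_coefficient(tg, mk, est)
  expect_equal(b_yx$b * b_xy$b, est$r^2, tolerance = 1e-10)

  # independent least-squares oracle
  x <- herd_values(herd, ta("live_weight_kg", 0))
  y <- herd_values(herd, ta("pre_slaughter_mass_kg"))[names(x)]
  ls <- unname(coef(lm(y ~ x))[2])
  expect_equal(b_yx$b, ls, tolerance = 1e-8)
})

test_that("forecast tables are affine in the marker with the anchor at the mean", {
  mk <- make_desc("live_weight_kg", 0L, 26, 5)
  targets <- list(
    list(stats = make_desc("slaughter_mass_kg", NA_integer_, 237.3, 33.3),
         coef = printed_coefficient(6.0, ta("live_weight_kg", 0),
                                    ta("slaughter_mass_kg"))),
    list(stats = make_desc("pulp_mass_kg", NA_integer_, 175.2, 26.1),
         coef = printed_coefficient(4.7, ta("live_weight_kg", 0),
                                    ta("pulp_mass_kg"))))
  tab <- build_forecast_table(mk, targets)
  expect_equal(tab$grid, 20:32)
  # anchor cell at the marker mean
  at_mean <- eval_forecast_table(tab, 26)
  expect_equal(unname(at_mean),
               c(237.3, 175.2))
  # adjacent cells differ by exactly b * step, so rows are monotone
  for (t in names(tab$rows)) {
    expect_equal(diff(tab$rows[[t]]$predicted),
                 rep(tab$rows[[t]]$b, 12))
    expect_true(all(diff(tab$rows[[t]]$predicted) > 0))
  }
  # linear evaluation is independent of the grid resolution
  tab_fine <- build_forecast_table(mk, targets, half_width = 3,
                                   step = 0.5)
  expect_equal(eval_forecast_table(tab, 24.3),
               eval_forecast_table(tab_fine, 24.3))
  # nearest mode reads the cell; off-grid values snap
  expect_equal(eval_forecast_table(tab, 24.3,
                                   interpolation = "nearest"),
               eval_forecast_table(tab, 24, interpolation = "nearest"))
  expect_warning(out <- eval_forecast_table(tab, 40,
                                            interpolation = "nearest"),
                 "outside")
  expect_equal(unname(out[1]), 237.3 + 6.0 * (40 - 26))
  expect_error(build_forecast_table(mk, targets, half_width = 0),
               "positive")
})

test_that("multi-marker forecasts average the per-marker predictions", {
  herd <- generate_herd(default_herd_config(200, seed = 29))
  fit <- herdcast(herd)
  mids <- names(fit$tables)
  mv <- setNames(c(521, 27, 70), mids)
  fc <- forecast_animal(fit$tables, mv)
  expect_equal(fc$combined, colMeans(fc$per_marker))
  # bounded by the per-marker extremes
  for (t in colnames(fc$per_marker)) {
    expect_gte(fc$combined[[t]], min(fc$per_marker[, t]))
    expect_lte(fc$combined[[t]], max(fc$per_marker[, t]))
  }
  # permutation invariance in the markers
  fc_rev <- forecast_animal(rev(fit$tables), rev(mv))
  expect_equal(fc_rev$combined[colnames(fc$per_marker)], fc$combined)
  # all markers at their fitted means -> the anchors exactly
  at_means <- forecast_animal(
    fit$tables,
    setNames(vapply(fit$marker_stats, function(s) s$mean, 0), mids))
  expect_equal(unname(at_means$combined),
               unname(vapply(fit$target_stats, function(s) s$mean, 0)))
  expect_error(forecast_animal(fit$tables, c(bogus_marker = 1)),
               "no forecast table")
})

test_that("forecast accuracy is percent agreement relative to the forecast", {
  expect_equal(forecast_accuracy(425.7, 425.7), 100)
  expect_equal(forecast_accuracy(100, 90), 90)
  expect_equal(forecast_accuracy(100, 110), 90)  # symmetric miss
  expect_error(forecast_accuracy(-1, 5), "positive")
  expect_error(forecast_accuracy(5, 0), "positive")
})

test_that("self-approbation recovers the herd means exactly", {
  herd <- generate_herd(default_herd_config(150, seed = 37))
  rep <- approbate(train = herd, test = herd, farm = "self")
  # mean combined forecast equals mean actual by the centring property
  expect_equal(rep$accuracy_pct, rep(100, 3), tolerance = 1e-8)
  expect_equal(rep$forecast_mean, rep$actual_mean, tolerance = 1e-8)
  expect_true(all(rep$per_animal_accuracy <= 100))
  # farm-level accuracy is definitionally the accuracy of the means
  expect_equal(rep$accuracy_pct,
               forecast_accuracy(rep$forecast_mean, rep$actual_mean))
})

test_that("farm-specific tables beat foreign tables on a shifted farm", {
  cfg_a <- default_herd_config(250, seed = 43)
  # an environmentally poorer farm: markers a little lighter, slaughter
  # outcomes depressed beyond what the markers explain
  cfg_b <- default_herd_config(250, seed = 44)
  cfg_b$vars$mean <- cfg_b$vars$mean * 0.96
  for (t in names(cfg_b$link$targets)) {
    m <- cfg_b$link$targets[[t]]$mean
    cfg_b$link$targets[[t]]$mean <- m * 0.96 - 0.04 * m
  }
  farm_a <- generate_herd(cfg_a)
  farm_b <- generate_herd(cfg_b)
  fit_a <- herdcast(farm_a)
  own <- approbate(train = farm_b, test = farm_b, farm = "B|B")
  foreign <- approbate(test = farm_b, external_tables = fit_a$tables,
                       farm = "B|A")
  expect_true(all(own$accuracy_pct >= foreign$accuracy_pct))
  expect_true(all(foreign$accuracy_pct < 100))
  expect_error(approbate(test = farm_b), "train or external_tables")
})
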