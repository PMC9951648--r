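test_that("describe returns the classical biometric indices", {
  herd <- tiny_herd()
  d <- describe(herd, "live_weight_kg", 0)  # values 20 26 32 25 27
  expect_equal(d$n, 5L)
  expect_equal(d$mean, 26)
  expect_equal(d$sd, sqrt(sum((c(20, 26, 32, 25, 27) - 26)^2) / 4))
  expect_equal(d$sem, d$sd / sqrt(5))

  # hand-computed three-point case with the n - 1 denominator
  three <- pair_herd(c(20, 26, 32, 26), c(1, 2, 3, 4))
  three$observations <- three$observations[
    !(three$observations$age_months == 0 &
        three$observations$animal_id == "C0004"), ]
  d3 <- describe(three, "live_weight_kg", 0)
  expect_equal(d3$mean, 26)
  expect_equal(d3$sd, 6)
  expect_equal(d3$sem, 6 / sqrt(3))

  # constant input: sd and sem are exactly zero
  const <- pair_herd(c(26, 26, 26, 26), c(1, 2, 3, 4))
  dc <- describe(const, "live_weight_kg", 0)
  expect_equal(c(dc$mean, dc$sd, dc$sem), c(26, 0, 0))

  one <- pair_herd(c(26, 27), c(1, 2))
  one$observations <- one$observations[-1, ]
  expect_error(describe(one, "live_weight_kg", 0), "at least 2")
})

test_that("correlate matches a direct sum-formula oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  est <- correlate(pair_herd(x, y), ta("live_weight_kg", 0),
                   ta("live_weight_kg", 18))
  n <- length(x)
  r_oracle <- (sum(x * y) - sum(x) * sum(y) / n) /
    sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  expect_equal(est$r, r_oracle, tolerance = 1e-12)
  expect_equal(est$m_r, (1 - r_oracle^2) / sqrt(n - 2), tolerance = 1e-12)

  # a batch of random small vectors against the same oracle
  set.seed(77)
  for (i in 1:20) {
    x <- 10 + rexp(8)
    y <- 10 + rexp(8)
    est <- correlate(pair_herd(x, y), ta("live_weight_kg", 0),
                     ta("live_weight_kg", 18))
    ro <- (sum(x * y) - sum(x) * sum(y) / 8) /
      sqrt((sum(x^2) - sum(x)^2 / 8) * (sum(y^2) - sum(y)^2 / 8))
    expect_lt(abs(est$r - ro), 1e-12)
  }
})

test_that("the error of r follows the zootechnical closed form", {
  # exact sample correlation 0.8 on n = 38 gives m_r = 0.36/6 = 0.06
  p <- exact_cor_pair(0.8, 38)
  est <- correlate(pair_herd(p$x, p$y), ta("live_weight_kg", 0),
                   ta("live_weight_kg", 18))
  expect_equal(est$r, 0.8, tolerance = 1e-10)
  expect_equal(est$m_r, 0.06, tolerance = 1e-10)
  expect_true(est$reliable)

  # m_r = 0 iff |r| = 1; m_r is maximal at r = 0 for fixed n
  ident <- correlate(pair_herd(p$x, 2 * p$x + 1),
                     ta("live_weight_kg", 0), ta("live_weight_kg", 18))
  expect_equal(ident$r, 1)
  expect_equal(ident$m_r, 0)
  expect_true(ident$reliable)
  p0 <- exact_cor_pair(0, 38)
  est0 <- correlate(pair_herd(p0$x, p0$y), ta("live_weight_kg", 0),
                    ta("live_weight_kg", 18))
  expect_gt(est0$m_r, est$m_r)
  expect_false(est0$reliable)
})

test_that("correlate is symmetric and affine-invariant", {
  set.seed(5)
  x <- 20 + 5 * runif(12)
  y <- 400 + 60 * runif(12)
  h <- pair_herd(x, y)
  a <- correlate(h, ta("live_weight_kg", 0), ta("live_weight_kg", 18))
  b <- correlate(h, ta("live_weight_kg", 18), ta("live_weight_kg", 0))
  expect_equal(a$r, b$r)
  expect_equal(a$m_r, b$m_r)
  h2 <- pair_herd(3 * x + 7, y)          # positive affine rescale
  a2 <- correlate(h2, ta("live_weight_kg", 0), ta("live_weight_kg", 18))
  expect_equal(a2$r, a$r, tolerance = 1e-12)
})

test_that("correlate rejects deficient input", {
  expect_error(correlate(pair_herd(1:3 + 10, c(1, 2, 3) + 10),
                         ta("live_weight_kg", 0),
                         ta("live_weight_kg", 18)),
               "at least 4")
  expect_error(correlate(pair_herd(rep(5, 6), 1:6),
                         ta("live_weight_kg", 0),
                         ta("live_weight_kg", 18)),
               "zero variance")
})

test_that("correlation tables are symmetric and complete", {
  herd <- generate_herd(default_herd_config(120, seed = 13))
  tbl <- correlation_table(herd, axis = "ages")
  ages <- herd_ages()
  expect_equal(nrow(tbl), choose(length(ages), 2))
  m <- cor_matrix(tbl)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))
  expect_true(all(m > 0))

  # per-group tables add one block per sire line
  tbl_g <- correlation_table(herd, axis = "ages",
                             grouping = "sire_line")
  expect_setequal(unique(tbl_g$group),
                  c("pooled", unique(herd$animals$sire_line)))

  # measurement-pair table within each age
  tbl_m <- correlation_table(herd, axis = "measurements")
  expect_true(all(tbl_m$r > 0.5))
  expect_equal(sum(tbl_m$group == "pooled"),
               length(herd_ages()) * choose(9, 2))
})

test_that("duplicated measurement columns give unit correlations", {
  ids <- sprintf("D%02d", 1:8)
  base <- c(68, 70, 72, 69, 71, 73, 70.5, 69.5)
  obs <- do.call(rbind, lapply(
    c("height_withers_cm", "height_sacrum_cm", "chest_depth_cm"),
    function(tr) data.frame(animal_id = ids, trait = tr,
                            age_months = 0L, value = base,
                            stringsAsFactors = FALSE)))
  herd <- herd_dataset(
    data.frame(animal_id = ids, sex = "M", sire_line = "L",
               bloodline = "B", dam_live_weight_kg = NA_real_,
               stringsAsFactors = FALSE), obs)
  tbl <- correlation_table(herd, axis = "measurements")
  expect_equal(tbl$r, rep(1, nrow(tbl)))
})

test_that("marker screening applies threshold and reliability jointly", {
  herd <- generate_herd(default_herd_config(800, seed = 17))
  ms <- screen_markers(herd)
  expect_length(ms$markers, 3L)
  expect_setequal(vapply(ms$markers, herdcast:::ta_id, character(1)),
                  c("dam_live_weight_kg", "live_weight_kg@0",
                    "height_withers_cm@0"))
  expect_true(all(ms$screen$reliable))

  all_pass <- screen_markers(herd, threshold = 0,
                             require_reliable = FALSE)
  expect_length(all_pass$markers, 3L)

  expect_warning(none <- screen_markers(herd, threshold = 0.99),
                 "no candidate")
  expect_length(none$markers, 0L)
})
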