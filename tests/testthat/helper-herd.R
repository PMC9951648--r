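# Hand-built fixtures used across the suite.

# five animals in two sire lines, live weight at birth and 18 months,
# no slaughter records
tiny_herd <- function() {
  ids <- paste0("B", 1:5)
  herd_dataset(
    animals = data.frame(
      animal_id = ids, sex = "M",
      sire_line = c("Line A", "Line A", "Line B", "Line B", "Line B"),
      bloodline = c("Black-and-White", "1/2 Holstein", "Black-and-White",
                    "1/2 Holstein", "1/4 Holstein"),
      dam_live_weight_kg = c(505, 512, 498, 520, 512),
      stringsAsFactors = FALSE),
    observations = rbind(
      data.frame(animal_id = ids, trait = "live_weight_kg",
                 age_months = 0L, value = c(20, 26, 32, 25, 27),
                 stringsAsFactors = FALSE),
      data.frame(animal_id = ids, trait = "live_weight_kg",
                 age_months = 18L, value = c(390, 425.7, 470, 410, 430),
                 stringsAsFactors = FALSE)),
    provenance = list(farm = "fixture"))
}

# construct a herd_desc / herd_cor directly, for closed-form unit tests
make_desc <- function(trait, age, mean, sd, n = 100) {
  structure(list(trait = trait, age_months = age, n = n, mean = mean,
                 sd = sd, sem = sd / sqrt(n)),
            class = "herd_desc")
}

make_cor <- function(pair_x, pair_y, r, n = 100) {
  m_r <- (1 - r^2) / sqrt(n - 2)
  structure(list(trait_x = ta_parse(pair_x), trait_y = ta_parse(pair_y),
                 n = n, r = r, m_r = m_r,
                 t_stat = if (m_r > 0) r / m_r else Inf,
                 reliable = TRUE, alpha = 0.05),
            class = "herd_cor")
}

# two vectors with an exactly prescribed sample correlation
exact_cor_pair <- function(r, n, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(2 * n), n, 2)
  z <- scale(z, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(z))
  x <- q[, 1]
  y <- r * q[, 1] + sqrt(1 - r^2) * q[, 2]
  list(x = 10 + 5 * x, y = 20 + 3 * y)
}

# wrap paired vectors into a herd so correlate() can be applied
pair_herd <- function(x, y) {
  ids <- sprintf("C%04d", seq_along(x))
  herd_dataset(
    animals = data.frame(animal_id = ids, sex = "M",
                         sire_line = "x", bloodline = "x",
                         dam_live_weight_kg = NA_real_,
                         stringsAsFactors = FALSE),
    observations = rbind(
      data.frame(animal_id = ids, trait = "live_weight_kg",
                 age_months = 0L, value = x, stringsAsFactors = FALSE),
      data.frame(animal_id = ids, trait = "live_weight_kg",
                 age_months = 18L, value = y,
                 stringsAsFactors = FALSE)))
}
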