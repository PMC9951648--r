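animals_sorted <- function(h) {
  a <- h$animals[order(h$animals$animal_id), ]
  rownames(a) <- NULL
  a
}

test_that("write/read round-trip preserves a herd field for field", {
  herd <- tiny_herd()
  dir <- withr::local_tempdir()
  write_herd(herd, dir)
  back <- read_herd(dir)
  expect_equal(animals_sorted(back), animals_sorted(herd))
  expect_equal(back$observations[order(back$observations$animal_id,
                                       back$observations$age_months), ],
               herd$observations[order(herd$observations$animal_id,
                                       herd$observations$age_months), ],
               ignore_attr = TRUE)
  expect_equal(nrow(back$slaughter), 0L)

  # a generated herd with slaughter records survives the trip too,
  # up to the 1-decimal rendering
  herd2 <- generate_herd(default_herd_config(20, seed = 3))
  dir2 <- withr::local_tempdir()
  write_herd(herd2, dir2)
  back2 <- read_herd(dir2)
  expect_equal(back2$slaughter$pre_slaughter_mass_kg,
               round_half_up(herd2$slaughter$pre_slaughter_mass_kg, 1))
  expect_equal(sort(back2$animals$animal_id),
               sort(herd2$animals$animal_id))
  # idempotence: a second trip is lossless exactly
  dir3 <- withr::local_tempdir()
  write_herd(back2, dir3)
  back3 <- read_herd(dir3)
  expect_equal(back3$observations$value, back2$observations$value)
})

test_that("numeric rendering matches the table convention", {
  herd <- tiny_herd()
  dir <- withr::local_tempdir()
  write_herd(herd, dir)
  obs_lines <- readLines(file.path(dir, "observations.csv"))
  expect_true(any(grepl("425.7", obs_lines, fixed = TRUE)))
  # integral values are written without a trailing .0
  expect_true(any(grepl(",390$", obs_lines)))
  # empty slaughter collection -> header-only file
  sl_lines <- readLines(file.path(dir, "slaughter.csv"))
  expect_length(sl_lines, 1L)
  expect_match(sl_lines, "^animal_id")
})

test_that("alternative delimiters round-trip", {
  herd <- tiny_herd()
  for (d in c("\t", ";")) {
    dir <- withr::local_tempdir()
    write_herd(herd, dir, delim = d)
    back <- read_herd(dir, delim = d)
    expect_equal(sort(back$animals$animal_id),
                 sort(herd$animals$animal_id))
    expect_equal(back$observations$value[order(back$observations$animal_id,
                                               back$observations$age_months)],
                 herd$observations$value[order(herd$observations$animal_id,
                                               herd$observations$age_months)])
  }
})

test_that("schema and referential errors are specific", {
  herd <- tiny_herd()
  dir <- withr::local_tempdir()
  write_herd(herd, dir)

  # drop a required column
  a <- utils::read.csv(file.path(dir, "animals.csv"))
  utils::write.csv(a[setdiff(names(a), "bloodline")],
                   file.path(dir, "animals.csv"), row.names = FALSE)
  expect_error(read_herd(dir), "bloodline")
  utils::write.csv(a, file.path(dir, "animals.csv"), row.names = FALSE)

  # corrupt one numeric cell: error carries column and line number
  lines <- readLines(file.path(dir, "observations.csv"))
  lines[3] <- sub("^([^,]+,[^,]+,[^,]+,).*$", "\\1twenty", lines[3])
  writeLines(lines, file.path(dir, "observations.csv"))
  expect_error(read_herd(dir), "value.*line 3")

  # an observation referencing an unknown animal names the id
  expect_error(
    herd_dataset(herd$animals,
                 rbind(herd$observations,
                       data.frame(animal_id = "GHOST",
                                  trait = "live_weight_kg",
                                  age_months = 0L, value = 25))),
    "GHOST")
  # missing file
  expect_error(read_herd(withr::local_tempdir()), "not found")
})

test_that("structural invariants are enforced", {
  herd <- tiny_herd()
  dup <- herd$animals[c(1, 1:5), ]
  expect_error(herd_dataset(dup, herd$observations), "duplicated")
  neg <- herd$observations
  neg$value[1] <- -3
  expect_error(herd_dataset(herd$animals, neg), "positive")
  dupobs <- rbind(herd$observations, herd$observations[1, ])
  expect_error(herd_dataset(herd$animals, dupobs), "duplicated")
  # composition bound on slaughter records
  sl <- generate_herd(default_herd_config(10, seed = 1))$slaughter
  sl$pulp_mass_kg[1] <- sl$chilled_carcass_mass_kg[1] * 1.5
  g <- generate_herd(default_herd_config(10, seed = 1))
  expect_error(herd_dataset(g$animals, g$observations, sl),
               "chilled carcass")
})

test_that("subset_by_group partitions the herd", {
  herd <- tiny_herd()
  expect_identical(subset_by_group(herd, "all"), herd)
  a <- subset_by_group(herd, "sire_line", "Line A")
  expect_equal(nrow(a$animals), 2L)
  expect_setequal(unique(a$observations$animal_id), a$animals$animal_id)
  expect_error(subset_by_group(herd, "sire_line", "Line Z"), "unknown")
  expect_error(subset_by_group(herd, "sire_line"), "level")
  for (grouping in c("sire_line", "bloodline")) {
    levels <- unique(herd$animals[[grouping]])
    parts <- lapply(levels, function(l)
      subset_by_group(herd, grouping, l)$animals$animal_id)
    expect_setequal(unlist(parts), herd$animals$animal_id)
    expect_equal(sum(lengths(parts)), nrow(herd$animals))  # no overlap
  }
})

test_that("herd_values pulls from the right table", {
  herd <- generate_herd(default_herd_config(15, seed = 2))
  v <- herd_values(herd, ta("dam_live_weight_kg"))
  expect_equal(unname(v), herd$animals$dam_live_weight_kg)
  v <- herd_values(herd, ta("pulp_mass_kg"))
  expect_equal(unname(v), herd$slaughter$pulp_mass_kg)
  v <- herd_values(herd, ta("live_weight_kg", 6))
  expect_length(v, 15)
  expect_error(ta("live_weight_kg", 5), "age")
  expect_error(ta("no_such_trait", 0), "unknown trait")
})
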