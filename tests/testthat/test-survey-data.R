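test_that("survey_dataset validates structure and referential integrity", {
  tb <- toy_tables()
  ds <- survey_dataset(tb$species, tb$pools, tb$visits, tb$samples)
  expect_s3_class(ds, "survey_dataset")
  expect_equal(nrow(ds$species), 2)
  expect_equal(ds$samples$k, c(1L, 2L, 1L, 2L))
  # imputed sample complexity flagged and taken from the pool
  expect_true(ds$samples$complexity_imputed[2])
  expect_equal(ds$samples$sample_complexity[2], 35)

  bad <- tb$samples
  bad$visit_id[1] <- "nope"
  expect_error(survey_dataset(tb$species, tb$pools, tb$visits, bad),
               "orphan reference")
  expect_error(survey_dataset(tb$species[, 1, drop = FALSE], tb$pools,
                              tb$visits, tb$samples), "missing column")
  bad2 <- tb$samples; bad2$effort_raw[3] <- 0
  expect_error(survey_dataset(tb$species, tb$pools, tb$visits, bad2),
               "effort_raw")
  bad3 <- tb$samples; bad3$seine_variant[1] <- "seine5m"
  expect_error(survey_dataset(tb$species, tb$pools, tb$visits, bad3),
               "seine_variant")
  badp <- tb$pools; badp$mesohabitat[1] <- 2
  expect_error(survey_dataset(tb$species, badp, tb$visits, tb$samples),
               "mesohabitat")
})

test_that("binarize_catch is the elementwise detection indicator", {
  expect_identical(binarize_catch(0L), 0L)
  expect_identical(binarize_catch(37L), 1L)
  expect_error(binarize_catch(c(1, -2)), "negative")
  set.seed(42)
  counts <- matrix(rpois(6, 1.5), 3, 2)
  expect_identical(binarize_catch(counts),
                   matrix(as.integer(counts >= 1), 3, 2))
  counts[2, 1] <- NA
  expect_true(is.na(binarize_catch(counts)[2, 1]))
})

test_that("rare-species filter removes two-visit species, keeps three", {
  # 3 species across 4 single-sample visits: spA detected at 3 visits,
  # spB at 2, spC at 1
  species <- data.frame(species_id = c("spA", "spB", "spC"),
                        mean_length = c(100, 200, 300))
  pools <- data.frame(pool_id = paste0("p", 1:4), mesohabitat = 0L,
                      max_depth = 2, turbidity = c(1, 2, 3, 4),
                      complexity = c(10, 20, 30, 40),
                      river_km = c(1, 2, 3, 4), conductivity = 300)
  visits <- data.frame(visit_id = paste0("v", 1:4),
                       pool_id = paste0("p", 1:4), year = 2018L)
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        visit_id = paste0("v", 1:4), gear = "seine_SM",
                        effort_raw = 10, sample_depth = 1,
                        sample_complexity = 10, seine_variant = "none")
  y <- array(0L, c(3, 4, 1))
  y[1, 1:3, 1] <- 1L   # spA: 3 site-visits
  y[2, c(1, 4), 1] <- 1L  # spB: 2 site-visits
  y[3, 2, 1] <- 1L     # spC: 1 site-visit
  ds <- survey_dataset(species, pools, visits, samples, y = y)

  expect_equal(unname(species_detection_events(ds)), c(3L, 2L, 1L))
  flt <- filter_rare_species(ds)
  expect_equal(flt$species$species_id, "spA")
  expect_setequal(attr(flt, "removed_species"), c("spB", "spC"))
  # idempotent
  again <- filter_rare_species(flt)
  expect_equal(again$species, flt$species)
  expect_equal(again$y, flt$y)
  # configurable threshold retains the two-visit species
  flt2 <- filter_rare_species(ds, min_events = 2)
  expect_setequal(flt2$species$species_id, c("spA", "spB"))
  expect_error(filter_rare_species(ds, 0), "min_events")
})

test_that("rare-species filter on an empty dataset is a no-op", {
  ds <- toy_dataset(scaled = FALSE)
  empty <- ds
  empty$species <- ds$species[0, ]
  empty$y <- ds$y[0, , , drop = FALSE]
  out <- filter_rare_species(empty)
  expect_equal(nrow(out$species), 0)
  expect_length(attr(out, "removed_species"), 0)
})

test_that("covariate scaling follows the documented conventions", {
  ds <- toy_dataset(scaled = FALSE)
  sc <- scale_covariates(ds)
  # depth divided by the maximum: 4.8 -> 1, 1.2 -> 0.25
  expect_equal(sc$pools$depth_s, c(1, 0.25))
  # two-value covariates standardize to symmetric +/- 1 (population SD)
  expect_equal(sc$pools$turbidity_s, c(-1, 1))
  expect_equal(sc$species$length_std, c(1, -1))
  # effort scaled per gear to (0, 1]
  expect_true(all(sc$samples$effort_s > 0 & sc$samples$effort_s <= 1))
  expect_true(all(sc$pools$depth_s > 0 & sc$pools$depth_s <= 1))
  # inverse transform recovers raw values
  raw <- unscale_covariates(sc)
  expect_equal(raw$max_depth, ds$pools$max_depth, tolerance = 1e-12)
  expect_equal(raw$turbidity, ds$pools$turbidity, tolerance = 1e-12)
  expect_equal(raw$effort_raw, ds$samples$effort_raw, tolerance = 1e-12)
  expect_equal(raw$mean_length, ds$species$mean_length,
               tolerance = 1e-12)
  # standardized columns have mean 0, SD 1 (population convention)
  for (v in list(sc$pools$turbidity_s, sc$pools$complexity_s,
                 sc$pools$river_km_s, sc$species$length_std)) {
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  }
  # zero-variance covariate is an error
  flat <- ds
  flat$pools$turbidity <- 5
  expect_error(scale_covariates(flat), "zero-variance")
})

test_that("effort scaling example: {60, 120, 240} s -> {0.25, 0.5, 1}", {
  tb <- toy_tables()
  tb$samples$gear <- "backpack_EF"
  tb$samples$seine_variant <- "none"
  tb$samples$effort_raw <- c(60, 120, 240, 240)
  ds <- survey_dataset(tb$species, tb$pools, tb$visits, tb$samples)
  sc <- scale_covariates(ds)
  expect_equal(sc$samples$effort_s, c(0.25, 0.5, 1, 1))
})

test_that("write/load round-trips survey tables bit-identically", {
  dir <- withr::local_tempdir()
  ds <- toy_dataset(scaled = FALSE)
  write_survey(ds, dir)
  back <- load_survey(dir)
  for (tab in c("species", "pools", "visits", "samples"))
    expect_identical(back[[tab]], ds[[tab]])
  expect_identical(back$y, ds$y)
  # and a second write of the loaded dataset is byte-identical
  dir2 <- withr::local_tempdir()
  write_survey(back, dir2)
  for (f in list.files(dir))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})

test_that("load_survey binarizes counts and rejects broken inputs", {
  dir <- withr::local_tempdir()
  tb <- toy_tables()
  ds0 <- survey_dataset(tb$species, tb$pools, tb$visits, tb$samples)
  write_survey(ds0, dir)
  write.csv(tb$catch, file.path(dir, "catch.csv"), row.names = FALSE)
  ds <- load_survey(dir)
  # detections match the direct indicator of the catch table
  expect_equal(ds$y["barra", "v1", 1:2], c(1L, 1L))
  expect_equal(ds$y["glassfish", "v2", 1:2], c(0L, 1L))
  expect_equal(sum(ds$y, na.rm = TRUE), 3)

  bad <- tb$catch
  bad$sample_id[1] <- "ghost"
  write.csv(bad, file.path(dir, "catch.csv"), row.names = FALSE)
  expect_error(load_survey(dir), "orphan reference")
  file.remove(file.path(dir, "catch.csv"))
  expect_error(load_survey(dir), "missing survey table")
})
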