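test_that("water-take rules modify depths as specified", {
  expect_equal(apply_min_depth_rule(c(2.0, 1.0), 1.65), c(1.65, 1.0))
  expect_equal(apply_min_depth_rule(c(0.5, 1.2), 2), c(0.5, 1.2))
  expect_equal(apply_min_depth_rule(c(0.5, 1.2), 0), c(0, 0))
  expect_error(apply_min_depth_rule(c(1, 2), -0.1), "rule")

  expect_equal(apply_percent_reduction(c(1, 2), 0.14), 0.86 * c(1, 2))
  expect_equal(apply_percent_reduction(c(1, 2), 0), c(1, 2))
  expect_equal(apply_percent_reduction(c(1, 2), 0.9), 0.1 * c(1, 2))
  expect_error(apply_percent_reduction(1, -0.2), "fraction")
  expect_error(apply_percent_reduction(1, 1.2), "fraction")
  expect_warning(apply_percent_reduction(1, 0.95), "policy range")
})

test_that("min-depth rule is monotone in the rule value", {
  set.seed(8)
  depths <- runif(20, 0.2, 5)
  rules <- sort(runif(15, 0, 3))
  mod <- sapply(rules, apply_min_depth_rule, depths_m = depths)
  # larger rule => elementwise deeper or equal pools
  expect_true(all(diff(t(mod)) >= 0))
})

test_that("expected occupied pools has the Poisson-occupancy closed form", {
  ds <- sim_small(1)
  p <- params_template(ds)
  # lambda = 0 at zero depth
  zero <- expected_occupied_pools(p, ds,
                                  depths_m = rep(0, nrow(ds$pools)))
  expect_equal(unname(zero), rep(0, nrow(ds$species)))
  # additive over disjoint pool sets and order-invariant
  ids <- ds$pools$pool_id
  full <- expected_occupied_pools(p, ds, ids)
  half <- expected_occupied_pools(p, ds, ids[1:10]) +
    expected_occupied_pools(p, ds, ids[-(1:10)])
  expect_equal(full, half, tolerance = 1e-12)
  perm <- expected_occupied_pools(p, ds, sample(ids))
  expect_equal(sort(perm), sort(full), tolerance = 1e-12)
})

test_that("distribution loss is a signed percent with NA at zero baseline", {
  expect_equal(distribution_loss(10, 9), 10)
  expect_equal(distribution_loss(7, 7), 0)
  expect_equal(distribution_loss(2, 2.2), -10)
  expect_true(is.na(distribution_loss(0, 1)))
})

test_that("scenario engine matches closed-form occupancy on a toy", {
  # two species, five main-channel pools, no random effects; the
  # single-parameter posterior collapses the engine to hand arithmetic
  species <- data.frame(species_id = c("deep", "shallow"),
                        mean_length = c(400, 50))
  pools <- data.frame(pool_id = paste0("p", 1:5), mesohabitat = 0L,
                      max_depth = c(0.8, 1.2, 2.0, 3.0, 4.0),
                      turbidity = 1:5, complexity = seq(5, 45, 10),
                      river_km = seq(10, 50, 10),
                      conductivity = seq(250, 450, 50))
  visits <- data.frame(visit_id = paste0("v", 1:5),
                       pool_id = paste0("p", 1:5), year = 2018L)
  samples <- data.frame(sample_id = paste0("s", 1:5),
                        visit_id = paste0("v", 1:5), gear = "seine_SM",
                        effort_raw = 10, sample_depth = 0.5,
                        sample_complexity = 10, seine_variant = "none")
  y <- array(0L, c(2, 5, 1))
  ds <- scale_covariates(
    survey_dataset(species, pools, visits, samples, y = y))
  p <- params_template(ds)
  p$beta[, 1] <- c(1, 1)
  p$beta[, 2] <- c(-0.5, 1.5)   # optima at scaled depth 1.65 and 0.22

  spec <- scenario_spec("min_depth", grid = c(0.5, 1.0, 1.65, 4.0))
  res <- suppressWarnings(objective_curve(p, spec, dataset = ds))

  # hand computation (same formulas, straight-line code)
  div <- ds$scaling$depth_divisor
  lam_hand <- function(i, depths) {
    Ds <- depths / div
    ifelse(Ds > 0,
           Ds * exp(p$beta[i, 1] - exp(p$beta[i, 2]) * Ds +
                      p$beta[i, 5] * ds$pools$turbidity_s +
                      p$beta[i, 7] * ds$pools$complexity_s +
                      p$beta[i, 9] * ds$pools$river_km_s), 0)
  }
  for (g in seq_along(spec$grid)) {
    mod <- pmin(pools$max_depth, spec$grid[g])
    for (i in 1:2) {
      base_i <- sum(1 - exp(-lam_hand(i, pools$max_depth)))
      scen_i <- sum(1 - exp(-lam_hand(i, mod)))
      row <- res$species[res$species$species_id ==
                           species$species_id[i] &
                           res$species$rule == spec$grid[g], ]
      expect_equal(row$loss, 100 * (base_i - scen_i) / base_i,
                   tolerance = 1e-10)
    }
  }
  # no-extraction endpoint (rule deeper than every pool): exactly 0
  endpoint <- res$species[res$species$rule == 4.0, ]
  expect_equal(endpoint$loss, c(0, 0))
  # the shallow-optimum species gains (negative loss) under drawdown
  shallow_row <- res$species[res$species$species_id == "shallow" &
                               res$species$rule == 0.5, ]
  expect_lt(shallow_row$loss, 0)
})

test_that("objective counting and per-species rules are consistent", {
  ds <- sim_small(1)
  tr <- ds$truth$params
  spec <- scenario_spec("percent_reduction",
                        grid = seq(0, 0.9, by = 0.1))
  res <- suppressWarnings(objective_curve(tr, spec, dataset = ds))
  expect_equal(res$kind, "percent_reduction")
  # f = 0 endpoint: every counted species has exactly zero loss and
  # meets every objective
  oc0 <- res$objective_counts[res$objective_counts$rule == 0, ]
  n_counted <- nrow(ds$species) - length(res$excluded)
  expect_true(all(oc0$n_species == n_counted))
  l0 <- res$species$loss[res$species$rule == 0]
  expect_equal(l0[!is.na(l0)], rep(0, sum(!is.na(l0))))
  # counts never exceed the counted species and never go negative
  expect_true(all(res$objective_counts$n_species >= 0 &
                    res$objective_counts$n_species <= n_counted))
  # per-species most liberal rule is on the grid or NA
  expect_true(all(is.na(res$species_rules$most_liberal_rule) |
                    res$species_rules$most_liberal_rule %in% spec$grid))
  expect_error(objective_curve(tr, scenario_spec("min_depth",
                                                 target_mesohabitat = 2),
                               dataset = ds), "empty target")
})
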