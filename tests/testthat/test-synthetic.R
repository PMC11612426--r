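test_that("design presets realize the emulated survey structure", {
  d <- make_design("fitzroy_like", seed = 1)
  expect_equal(nrow(d$pools), 59)
  expect_equal(sum(d$pools$mesohabitat == 0), 20)
  expect_equal(sum(d$pools$mesohabitat == 1), 39)
  expect_equal(nrow(d$visits), 107)
  expect_equal(nrow(d$species), 21)
  expect_true(all(d$visits$year %in% 2018:2021))
  # per-visit sample counts between 2 and 18
  k <- table(d$samples$visit_id)
  expect_true(all(k >= 2 & k <= 18))
  # mesohabitat depth ranges
  mc <- d$pools$max_depth[d$pools$mesohabitat == 0]
  fp <- d$pools$max_depth[d$pools$mesohabitat == 1]
  expect_true(all(mc >= 0.35 & mc <= 4.8))
  expect_true(all(fp >= 0.1 & fp <= 3.5))
  # boat electrofishing allocated only to samples deeper than 1 m
  expect_true(all(d$samples$sample_depth[d$samples$gear == "boat_EF"] > 1))
  # seine variants only on the large-mesh seine
  expect_true(all((d$samples$seine_variant != "none") ==
                    (d$samples$gear == "seine_LM")))
  expect_error(make_design("nope"), "arg")
})

test_that("tiny preset is small and deterministic given the seed", {
  d1 <- make_design("tiny", seed = 5)
  d2 <- make_design("tiny", seed = 5)
  expect_equal(nrow(d1$pools), 3)
  expect_equal(nrow(d1$species), 2)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$pools, d2$pools)
  d3 <- make_design("tiny", seed = 6)
  expect_false(identical(d1$pools$max_depth, d3$pools$max_depth))
})

test_that("generated designs pass survey validation unchanged", {
  for (p in c("tiny", "fitzroy_small")) {
    d <- make_design(p, seed = 3)
    rebuilt <- survey_dataset(d$species, d$pools, d$visits,
                              d$samples[setdiff(names(d$samples), "k")])
    expect_s3_class(rebuilt, "survey_dataset")
  }
  sim <- sim_small(1)
  rebuilt <- survey_dataset(sim$species, sim$pools, sim$visits,
                            sim$samples[setdiff(names(sim$samples),
                                                "k")], y = sim$y)
  expect_s3_class(rebuilt, "survey_dataset")
})

test_that("truth parameters follow the fourth-corner hierarchy", {
  d <- scale_covariates(make_design("fitzroy_small", 1))
  # zero spread collapses coefficients onto the length-explained mean
  hz <- default_truth_hyper()
  hz$hyper$sigma <- 0
  tr <- draw_parameters(d, hz, seed = 2)
  L <- d$species$length_std
  h <- hz$hyper
  expect_equal(unname(tr$beta[, 1]),
               h$eta1[h$family == "beta1"] +
                 h$eta2[h$family == "beta1"] * L, tolerance = 1e-12)
  expect_equal(unname(tr$phi$boat_EF[, 2]),
               h$eta1[h$family == "phi2.boat_EF"] +
                 h$eta2[h$family == "phi2.boat_EF"] * L,
               tolerance = 1e-12)
  # determinism
  expect_equal(draw_parameters(d, seed = 7), draw_parameters(d, seed = 7))
  # CLT: across replicate draws, mean residual of beta1 from its
  # hierarchy mean is 0 within 3 SE (sigma = 0.3, 150 x 12 draws)
  hy <- default_truth_hyper()
  resid <- unlist(lapply(1:150, function(s) {
    b1 <- draw_parameters(d, hy, seed = 1000 + s)$beta[, 1]
    b1 - (hy$hyper$eta1[1] + hy$hyper$eta2[1] * L)
  }))
  expect_lt(abs(mean(resid)), 3 * 0.3 / sqrt(length(resid)))
  bad <- default_truth_hyper(); bad$sigma_pool <- -1
  expect_error(draw_parameters(d, bad, seed = 1), "sigma")
})

test_that("simulated surveys follow the generative chain", {
  sim <- sim_small(1)
  expect_true(all(sim$y[!is.na(sim$y)] %in% 0:1))
  expect_equal(dim(sim$truth$N), dim(sim$truth$lambda))
  # detections only where latent abundance is positive
  st <- sim$truth
  sa <- sim$samples
  visit_of <- match(sa$visit_id, sim$visits$visit_id)
  for (n in seq_len(nrow(sa))) {
    yv <- sim$y[, visit_of[n], sa$k[n]]
    expect_true(all(yv[st$N[, visit_of[n]] == 0] == 0))
  }
  # deterministic given seed
  d <- scale_covariates(make_design("tiny", 4))
  s1 <- simulate_survey(d, seed = 9)
  s2 <- simulate_survey(d, seed = 9)
  expect_identical(s1$y, s2$y)
})

test_that("a collapsed abundance model yields no detections", {
  d <- scale_covariates(make_design("tiny", 2))
  tr <- draw_parameters(d, seed = 3)
  tr$beta[, 1] <- -40  # lambda ~ 0 everywhere
  sim <- simulate_survey(d, tr, seed = 5)
  expect_equal(sum(sim$y, na.rm = TRUE), 0)
})

test_that("simulator matches analytic detection marginals", {
  # single visit replicated: r = 1, lambda = 5 detects with prob 1-e^-5
  lambda <- 5; B <- 20000
  set.seed(31)
  N <- rpois(B, lambda)
  y <- rbinom(B, 1, detection_prob(rep(1, B), N))
  p_true <- 1 - exp(-lambda)
  se <- sqrt(p_true * (1 - p_true) / B)
  expect_lt(abs(mean(y) - p_true), 3 * se)

  # a random small configuration against the truncated-sum marginal
  set.seed(32)
  lam2 <- runif(1, 0.5, 4); r2 <- runif(1, 0.05, 0.6)
  N2 <- rpois(B, lam2)
  y2 <- rbinom(B, 1, detection_prob(rep(r2, B), N2))
  p2 <- marginal_detection_prob(lam2, r2)
  se2 <- sqrt(p2 * (1 - p2) / B)
  expect_lt(abs(mean(y2) - p2), 3 * se2)
})

test_that("abundance is monotone below the Ricker peak", {
  # species whose scaled optimum is >= 1 never decline over the
  # observed depth range
  b <- rep(0, 10); b[2] <- -0.3  # D* = e^{0.3} > 1
  D <- seq(0.01, 1, length.out = 200)
  ll <- sapply(D, function(dd)
    abundance_linpred(b, list(depth_s = dd, mesohabitat = 0,
                              turbidity_s = 0, complexity_s = 0,
                              river_km_s = 0)))
  expect_true(all(diff(ll) > 0))
  # mean simulated N is nondecreasing in depth on the lambda scale
  lam <- exp(ll)
  expect_true(all(diff(lam) > 0))
})
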