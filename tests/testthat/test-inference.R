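test_that("default priors enumerate the full hyperparameter structure", {
  ds <- toy_dataset()
  pr <- default_priors(ds)
  # 32 coefficient families (10 abundance + 6+6+5+5 observation), each
  # with an (eta1, eta2, sigma) triple, plus 4 effort exponents, the 5-m
  # seine scalar, and 2 random-effect spreads
  expect_length(pr$families, 32)
  expect_equal(pr$eta1_sd, 2)
  expect_equal(pr$eta2_sd, 1)
  expect_equal(pr$sigma_s_scale, 0.5)
  expect_equal(pr$upsilon_bounds, c(0, 1))
  over <- default_priors(ds, eta1_sd = 5)
  expect_equal(over$eta1_sd, 5)
  expect_error(default_priors(ds, eta1_sd = -1), "scales")

  # finite at interior values, -Inf at the sigma boundary
  p <- params_template(ds)
  ds2 <- scale_covariates(toy_dataset(scaled = FALSE))
  expect_true(is.finite(joint_log_posterior(p, ds2, pr)))
  p$hyper$sigma[4] <- 0
  expect_identical(joint_log_posterior(p, ds2, pr), -Inf)
})

test_that("split R-hat flags disagreement and handles degeneracy", {
  set.seed(1)
  m <- matrix(rnorm(40000), 10000, 4)
  expect_gt(rhat(m), 0.99)
  expect_lt(rhat(m), 1.01)
  shifted <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(rhat(shifted), 1.5)
  expect_true(is.na(rhat(matrix(1, 100, 4))))
  expect_error(rhat(matrix(rnorm(4), 2, 2)[, 1, drop = FALSE]))
})

test_that("ESS tracks independent and autocorrelated chains", {
  set.seed(2)
  m <- matrix(rnorm(4000), 1000, 4)
  e <- ess(m)
  expect_gt(e, 0.8 * 4000)
  expect_lt(e, 1.25 * 4000)
  # AR(1) with rho = 0.9: ESS ~ n (1-rho)/(1+rho)
  rho <- 0.9
  n <- 20000
  ar <- sapply(1:4, function(i) {
    as.numeric(arima.sim(list(ar = rho), n))
  })
  target <- 4 * n * (1 - rho) / (1 + rho)
  expect_gt(ess(ar), 0.7 * target)
  expect_lt(ess(ar), 1.3 * target)
  expect_true(is.na(ess(matrix(1, 100, 4))))
})

test_that("ESS and R-hat agree with coda on a common case", {
  set.seed(3)
  ar <- sapply(1:4, function(i) as.numeric(arima.sim(list(ar = 0.7),
                                                     2000)))
  ours <- ess(ar)
  coda_est <- sum(apply(ar, 2, function(v)
    coda::effectiveSize(coda::mcmc(v))))
  expect_lt(abs(ours - coda_est) / coda_est, 0.35)
})

test_that("run_mcmc is a reproducible, validated smoke contract", {
  ds <- sim_small(2)
  cfg <- mcmc_config(n_chains = 2, n_warmup = 60, n_draws = 60, seed = 9)
  fit1 <- suppressWarnings(run_mcmc(ds, config = cfg))
  expect_s3_class(fit1, "pf_posterior")
  expect_true(all(is.finite(posterior_matrix(fit1))))
  expect_equal(nrow(fit1$diagnostics), length(fit1$par_names))
  # same seed twice: bit-identical draws
  fit2 <- suppressWarnings(run_mcmc(ds, config = cfg))
  expect_identical(fit1$draws, fit2$draws)
  expect_error(mcmc_config(n_chains = 1), "n_chains")
  # stored log-posterior matches the R reference on a draw
  p5 <- posterior_params(fit1, chain = 1, draw = 5)
  expect_equal(joint_log_posterior(p5, ds, fit1$priors),
               fit1$lp[5, 1], tolerance = 1e-6)
})

test_that("with no data the posterior reproduces the prior", {
  # a dataset with pools and species but zero visits: the sampler sees
  # only the prior, so eta1 moments must match Normal(0, 2^2)
  ds <- sim_small(1)
  ds$visits <- ds$visits[0, ]
  ds$samples <- ds$samples[0, ]
  ds$y <- array(0L, c(nrow(ds$species), 0, 0))
  fit <- suppressWarnings(run_mcmc(ds, config = mcmc_config(
    n_chains = 2, n_warmup = 300, n_draws = 1200, seed = 4,
    am_reps = 8, seesaw_reps = 4)))
  m <- posterior_matrix(fit)
  eta1 <- m[, grepl("^eta1\\[", colnames(m))]
  # pooled over the 32 exchangeable families to cut MC error; the
  # joint block moves correlate families within a sweep, so the
  # effective sample size behind the pooled sd is that of a single
  # trajectory (~hundreds), giving ~0.1 SE on a sd of 2
  expect_lt(abs(mean(eta1)), 0.2)
  expect_lt(abs(sd(as.vector(eta1)) - 2), 0.35)
  eta2 <- m[, grepl("^eta2\\[", colnames(m))]
  expect_lt(abs(sd(as.vector(eta2)) - 1), 0.2)
  # upsilon recovers its uniform prior mean
  expect_lt(abs(mean(m[, "upsilon[boat_EF]"]) - 0.5), 0.1)
})

test_that("Gibbs and Metropolis hyperparameter updates agree", {
  ds <- sim_small(3)
  cfg_g <- mcmc_config(n_chains = 2, n_warmup = 250, n_draws = 450,
                       seed = 11, gibbs_hyper = TRUE,
                       am_reps = 8, seesaw_reps = 4)
  cfg_m <- mcmc_config(n_chains = 2, n_warmup = 250, n_draws = 450,
                       seed = 12, gibbs_hyper = FALSE,
                       am_reps = 8, seesaw_reps = 4)
  fit_g <- suppressWarnings(run_mcmc(ds, config = cfg_g))
  fit_m <- suppressWarnings(run_mcmc(ds, config = cfg_m))
  # the two kernels target the same posterior: compare a stable summary
  for (p in c("upsilon[seine_LM]", "upsilon[seine_SM]", "lm_scalar")) {
    mg <- fit_g$diagnostics[fit_g$diagnostics$parameter == p, ]
    mm <- fit_m$diagnostics[fit_m$diagnostics$parameter == p, ]
    expect_lt(abs(mg$mean - mm$mean),
              3 * sqrt(mg$sd^2 / mg$ess + mm$sd^2 / mm$ess) + 0.02)
  }
})

test_that("posterior draws serialize to delimited tables", {
  ds <- sim_small(2)
  fit <- suppressWarnings(run_mcmc(ds, config = mcmc_config(
    n_chains = 2, n_warmup = 30, n_draws = 20, seed = 1)))
  dir <- withr::local_tempdir()
  write_posterior(fit, dir)
  expect_true(all(file.exists(file.path(dir,
    c("draws.csv", "diagnostics.csv", "fit_meta.csv", "scaling.csv")))))
  dr <- read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  expect_equal(nrow(dr), 40)
  expect_equal(dr[["eta1[beta1]"]],
               c(fit$draws[[1]][, "eta1[beta1]"],
                 fit$draws[[2]][, "eta1[beta1]"]))
})
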