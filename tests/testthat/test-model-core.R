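test_that("abundance linear predictor follows the Ricker depth form", {
  pc <- list(depth_s = 1, mesohabitat = 0, turbidity_s = 0,
             complexity_s = 0, river_km_s = 0)
  b <- rep(0, 10)
  expect_equal(abundance_linpred(b, pc), -1)
  pc$depth_s <- 0.5
  expect_equal(abundance_linpred(b, pc), log(0.5) - 0.5)
  # floodplain intercept offset is additive
  b2 <- b; b2[3] <- 1
  pc2 <- list(depth_s = 1, mesohabitat = 1, turbidity_s = 0,
              complexity_s = 0, river_km_s = 0)
  expect_equal(abundance_linpred(b2, pc2), 0)
  # zero depth gives lambda = 0 (log-lambda -Inf), negatives rejected
  pc$depth_s <- 0
  expect_equal(abundance_linpred(b, pc), -Inf)
  pc$depth_s <- -0.1
  expect_error(abundance_linpred(b, pc), "depth")
})

test_that("peak_depth is the analytic maximizer of the Ricker term", {
  expect_equal(peak_depth(0, 0), 1)
  expect_equal(peak_depth(log(2), 0, 0), 0.5)
  expect_equal(peak_depth(-0.5, 0.5, 1), 1)
  # numerical argmax over a fine grid matches for random draws
  set.seed(7)
  for (i in 1:25) {
    b2 <- rnorm(1); b4 <- rnorm(1, 0, 0.5); M <- rbinom(1, 1, 0.5)
    dstar <- peak_depth(b2, b4, M)
    f <- function(D) log(D) - exp(b2 + b4 * M) * D
    opt <- stats::optimize(f, c(dstar / 2, dstar * 2), maximum = TRUE,
                           tol = 1e-10)
    expect_equal(opt$maximum, dstar, tolerance = 1e-6)
  }
})

test_that("catchability predictor handles gear-specific terms", {
  sc <- list(sample_depth_s = 1, turbidity_s = 0,
             sample_complexity_s = 0, conductivity_s = 0)
  expect_equal(catchability_linpred(rep(0, 6), sc, "boat_EF"), -1)
  # linear and quadratic turbidity terms cancel at T = 1
  sc2 <- sc; sc2$turbidity_s <- 1
  expect_equal(catchability_linpred(c(0, 0, 1, -1, 0, 0), sc2,
                                    "boat_EF"), -1)
  # conductivity is an electrofishing-only term
  expect_error(catchability_linpred(rep(0, 6), sc, "seine_SM"),
               "length 5")
  sc3 <- sc; sc3$conductivity_s <- 1.2
  expect_error(catchability_linpred(rep(0, 5), sc3, "seine_SM"),
               "electrofishing")
  sc4 <- sc; sc4$sample_depth_s <- 0
  expect_error(catchability_linpred(rep(0, 6), sc4, "boat_EF"), "depth")
})

test_that("capture probability scales with effort as upsilon dictates", {
  lq <- log(0.22314)
  # upsilon = 0: no effort relationship
  expect_equal(capture_prob(lq, 0.1, 0), capture_prob(lq, 1, 0))
  # closed form at full effort
  expect_equal(capture_prob(lq, 1, 1), 1 - exp(-0.22314),
               tolerance = 1e-10)
  # E = 0.25, upsilon = 0.5 halves it
  expect_equal(capture_prob(lq, 0.25, 0.5),
               0.5 * (1 - exp(-0.22314)), tolerance = 1e-10)
  # the 5-m seine scalar multiplies exactly
  expect_equal(capture_prob(lq, 0.25, 0.5, lm_scalar = 0.6),
               0.6 * capture_prob(lq, 0.25, 0.5), tolerance = 1e-15)
  expect_error(capture_prob(lq, 1, 1.5), "upsilon")
  expect_error(capture_prob(lq, 1, 1, lm_scalar = 0), "lm_scalar")
  # monotone nondecreasing in E for upsilon > 0
  E <- seq(0, 1, 0.05)
  expect_true(all(diff(capture_prob(lq, E, 0.7)) >= 0))
})

test_that("detection probability p = 1 - (1-r)^N with stable limits", {
  expect_equal(detection_prob(0.37, 0), 0)
  expect_equal(detection_prob(1, 5), 1)
  expect_equal(detection_prob(0.2, 3), 0.488)
  # nondecreasing in N and in r
  expect_true(all(diff(detection_prob(0.2, 0:50)) >= 0))
  expect_true(all(diff(detection_prob(seq(0, 1, 0.01), 3)) >= 0))
})

test_that("marginal unit likelihood matches closed forms", {
  expect_equal(marginal_loglik_unit(2.5, 1, 0), -2.5)
  # r = 1 is clipped to 1 - 1e-12 internally, which perturbs the value
  # at that order
  expect_equal(marginal_loglik_unit(1, 1, 1), log(1 - exp(-1)),
               tolerance = 1e-9)
  expect_equal(marginal_loglik_unit(0, c(0.5, 0.5), c(0, 0)), 0)
  expect_equal(marginal_loglik_unit(0, c(0.5, 0.5), c(1, 0)), -Inf)
})

test_that("marginal unit likelihood equals brute-force enumeration", {
  set.seed(11)
  for (i in 1:40) {
    K <- sample(1:4, 1)
    lambda <- runif(1, 0, 10)
    r <- runif(K)
    y <- rbinom(K, 1, 0.5)
    expect_equal(marginal_loglik_unit(lambda, r, y),
                 brute_unit_loglik(lambda, r, y, 500),
                 tolerance = 1e-8)
  }
})

test_that("unit likelihood is sample-order invariant and truncation-stable", {
  set.seed(3)
  lambda <- 2.5; r <- runif(3); y <- c(1, 0, 1)
  base <- marginal_loglik_unit(lambda, r, y)
  perm <- sample(3)
  expect_equal(marginal_loglik_unit(lambda, r[perm], y[perm]), base,
               tolerance = 1e-12)
  # increasing N_max beyond the adaptive choice changes nothing
  expect_equal(marginal_loglik_unit(lambda, r, y, N_max = 2000), base,
               tolerance = 1e-8)
})

test_that("single-sample unit likelihood reduces to the Royle-Nichols form", {
  # one gear, one sample, no effort dependence: P(y=1) is the N-marginal
  # of 1 - (1-r)^N under Poisson abundance
  lambda <- 1.7; r <- capture_prob(log(0.3), 0.4, 0)
  direct <- sum(dpois(0:400, lambda) * (1 - (1 - r)^(0:400)))
  expect_equal(marginal_loglik_unit(lambda, r, 1), log(direct),
               tolerance = 1e-10)
  expect_equal(marginal_loglik_unit(lambda, r, 0), log(1 - direct),
               tolerance = 1e-10)
})

test_that("fourth-corner log-prior matches direct normal sums", {
  L <- c(-1, 0, 1)
  # coefficients at the mean: n x standard normal log-density at 0
  expect_equal(fourth_corner_logprior(rep(2, 3), 2, 0, 1, L),
               3 * dnorm(0, log = TRUE))
  # mean structure eta1 + eta2 * L reproduced exactly
  co <- 0.5 + 1.5 * L
  expect_equal(fourth_corner_logprior(co, 0.5, 1.5, 0.7, L),
               3 * dnorm(0, 0, 0.7, log = TRUE))
  set.seed(5)
  co <- rnorm(6); Ls <- rnorm(6)
  expect_equal(fourth_corner_logprior(co, 0.3, -0.2, 0.9, Ls),
               sum(dnorm(co, 0.3 - 0.2 * Ls, 0.9, log = TRUE)))
  expect_error(fourth_corner_logprior(co, 0, 0, 0, Ls), "sigma")
})

test_that("joint log posterior assembles likelihood and priors", {
  ds <- sim_small(1)
  pr <- default_priors(ds)
  p <- params_template(ds)
  # hand-assembled: all-zero coefficients, template spreads
  lp <- joint_log_posterior(p, ds, pr)
  h <- p$hyper
  expected_prior <-
    sum(vapply(seq_len(nrow(h)), function(s)
      fourth_corner_logprior(poolfish:::family_column(p, h$family[s]),
                             h$eta1[s], h$eta2[s], h$sigma[s],
                             ds$species$length_std), numeric(1))) +
    sum(dnorm(p$eps_pool, 0, p$sigma_pool, log = TRUE)) +
    sum(dnorm(p$eps_time, 0, p$sigma_time, log = TRUE)) +
    sum(dnorm(h$eta1, 0, pr$eta1_sd, log = TRUE)) +
    sum(dnorm(h$eta2, 0, pr$eta2_sd, log = TRUE)) +
    sum(poolfish:::dhalfnorm_log(h$sigma, pr$sigma_s_scale)) +
    poolfish:::dhalfnorm_log(p$sigma_pool, pr$sigma_pool_scale) +
    poolfish:::dhalfnorm_log(p$sigma_time, pr$sigma_time_scale)
  expect_equal(lp, expected_prior + loglik_dataset(p, ds),
               tolerance = 1e-10)

  # zero-visit dataset gives the prior-only value
  ds0 <- ds
  ds0$visits <- ds$visits[0, ]
  ds0$samples <- ds$samples[0, ]
  ds0$y <- NULL
  p0 <- p
  p0$eps_time <- p$eps_time[0]
  lp0 <- joint_log_posterior(p0, ds0, pr)
  expect_true(is.finite(lp0))

  # non-finite parameters yield -Inf, not an error
  pbad <- p; pbad$beta[1, 1] <- NaN
  expect_identical(joint_log_posterior(pbad, ds, pr), -Inf)
  pbad2 <- p; pbad2$upsilon[1] <- 1.2
  expect_identical(joint_log_posterior(pbad2, ds, pr), -Inf)
})

test_that("all-zero detection histories lose likelihood as lambda grows", {
  r <- c(0.3, 0.2)
  y <- c(0, 0)
  lls <- sapply(c(0.5, 1, 2, 4), marginal_loglik_unit, r = r, y = y)
  expect_true(all(diff(lls) < 0))
})

test_that("compiled likelihood agrees with the R reference", {
  ds <- sim_small(1)
  tr <- ds$truth$params
  pr <- default_priors(ds)
  data <- poolfish:::model_data_list(ds)
  ctl <- poolfish:::cpp_control(mcmc_config(seed = 1))
  llR <- loglik_dataset(tr, ds)
  llC <- poolfish:::cpp_loglik_total(data, poolfish:::params_to_cpp(tr),
                                     unclass(pr), ctl)
  expect_equal(llR, llC, tolerance = 1e-8)
  lpR <- joint_log_posterior(tr, ds, pr)
  lpC <- poolfish:::cpp_log_posterior(data, poolfish:::params_to_cpp(tr),
                                      unclass(pr), ctl)
  expect_equal(lpR, lpC, tolerance = 1e-8)
})

test_that("parameter sets flatten, unflatten and serialize losslessly", {
  ds <- sim_small(1)
  tr <- ds$truth$params
  v <- flatten_params(tr)
  back <- unflatten_params(v, ds)
  expect_equal(back, tr, tolerance = 1e-15)
  f <- withr::local_tempfile(fileext = ".csv")
  write_params(tr, f)
  back2 <- read_params(f, ds)
  expect_equal(flatten_params(back2), v, tolerance = 1e-12)
  expect_error(unflatten_params(v[-1], ds), "missing parameter")
})
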