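# Shared fixtures, built in code.

# A hand-built 2-species x 2-pool survey with one visit per pool and two
# samples per visit; counts chosen so detection patterns are asymmetric.
toy_tables <- function() {
  species <- data.frame(species_id = c("barra", "glassfish"),
                        mean_length = c(420, 35))
  pools <- data.frame(pool_id = c("p1", "p2"),
                      mesohabitat = c(0L, 1L),
                      max_depth = c(4.8, 1.2),
                      turbidity = c(12, 60),
                      complexity = c(35, 10),
                      river_km = c(80, 150),
                      conductivity = c(310, 520))
  visits <- data.frame(visit_id = c("v1", "v2"),
                       pool_id = c("p1", "p2"),
                       year = c(2018L, 2019L))
  samples <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    visit_id = c("v1", "v1", "v2", "v2"),
    gear = c("boat_EF", "seine_LM", "backpack_EF", "seine_SM"),
    effort_raw = c(600, 25, 300, 40),
    sample_depth = c(2.5, 1.4, 0.6, 0.8),
    sample_complexity = c(20, NA, 50, 5),
    seine_variant = c("none", "seine5m", "none", "none"))
  catch <- data.frame(
    species_id = c("barra", "barra", "glassfish"),
    sample_id = c("s1", "s2", "s4"),
    count = c(3L, 1L, 12L))
  list(species = species, pools = pools, visits = visits,
       samples = samples, catch = catch)
}

toy_dataset <- function(scaled = TRUE) {
  tb <- toy_tables()
  ds <- survey_dataset(tb$species, tb$pools, tb$visits, tb$samples)
  y <- poolfish:::detection_array_from_catch(ds, tb$catch, "count")
  ds <- survey_dataset(tb$species, tb$pools, tb$visits, tb$samples,
                       y = y)
  if (scaled) ds <- scale_covariates(ds)
  ds
}

# Independent brute-force oracle for the marginalized unit likelihood:
# direct enumeration of the Poisson-Bernoulli mixture to N = n_max.
brute_unit_loglik <- function(lambda, r, y, n_max = 500) {
  total <- 0
  for (N in 0:n_max) {
    p <- 1 - (1 - r)^N
    lik <- prod(ifelse(y == 1, p, 1 - p))
    total <- total + dpois(N, lambda) * lik
  }
  log(total)
}

# One simulated small survey with truth attached, memoised per seed so
# multiple test files can share it without refitting.
.sim_cache <- new.env(parent = emptyenv())
sim_small <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.sim_cache[[key]])) {
    d <- scale_covariates(make_design("fitzroy_small", seed))
    tr <- draw_parameters(d, seed = seed + 100)
    .sim_cache[[key]] <- simulate_survey(d, tr, seed = seed + 200)
  }
  .sim_cache[[key]]
}

# Truth values of the default generating hyperparameters, flattened for
# comparisons against posterior summaries.
truth_hyper_values <- function(truth_params) {
  h <- truth_params$hyper
  c(stats::setNames(h$eta1, sprintf("eta1[%s]", h$family)),
    stats::setNames(h$eta2, sprintf("eta2[%s]", h$family)),
    stats::setNames(truth_params$upsilon,
                    sprintf("upsilon[%s]", names(truth_params$upsilon))),
    lm_scalar = truth_params$lm_scalar)
}
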