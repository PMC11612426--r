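#' Default generating hyperparameters for synthetic surveys
#'
#' Preset truth values for the species hierarchy used by the simulator.
#' They encode the qualitative structure the model is designed to
#' express -- smaller species reach higher peak abundances, larger
#' species peak in deeper water (negative length slope on the Ricker
#' log-decay families), turbidity depresses abundance, floodplain pools
#' hold fewer fish, and gear-level mean catchabilities sit near
#' backpack 0.03 / boat 0.06 / large-mesh 0.21 / small-mesh 0.15 --
#' without claiming any fitted real-data values.
#'
#' @param ... Overrides: any of `sigma_pool`, `sigma_time`, `upsilon`
#'   (named length-4), `lm_scalar`, or rows of `hyper` via
#'   `hyper = data.frame(...)`.
#' @return List with `hyper` (32-row data.frame: family, eta1, eta2,
#'   sigma), `sigma_pool`, `sigma_time`, `upsilon`, `lm_scalar`.
#' @export
default_truth_hyper <- function(...) {
  fam <- pf_families()
  h <- data.frame(family = fam, eta1 = 0, eta2 = 0, sigma = 0.3,
                  stringsAsFactors = FALSE)
  set_fam <- function(h, f, e1, e2, s = 0.3) {
    h[h$family == f, c("eta1", "eta2", "sigma")] <- list(e1, e2, s); h
  }
  h <- set_fam(h, "beta1", 2.5, -0.5)   # peak abundance, higher for small
  h <- set_fam(h, "beta2", 0.5, -0.8)   # large species peak deeper
  h <- set_fam(h, "beta3", -0.7, -0.3)  # floodplain holds fewer fish
  h <- set_fam(h, "beta4", 0.2, 0.2)
  h <- set_fam(h, "beta5", -0.5, -0.2)  # turbidity depresses abundance
  h <- set_fam(h, "beta6", -0.2, 0.0)
  h <- set_fam(h, "beta7", 0.2, -0.3)   # complexity helps small species
  h <- set_fam(h, "beta8", -0.2, 0.1)
  # phi1: gear mean catchability anchors (backpack/boat/LM/SM)
  h <- set_fam(h, "phi1.backpack_EF", -2.3, -0.3)
  h <- set_fam(h, "phi1.boat_EF", -1.6, 0.2)
  h <- set_fam(h, "phi1.seine_LM", -0.4, 0.2)
  h <- set_fam(h, "phi1.seine_SM", -0.7, -0.3)
  for (g in pf_gears()) {
    h <- set_fam(h, paste0("phi2.", g), 0.3, -0.5)  # depth-length
    h <- set_fam(h, paste0("phi3.", g), 0.3, 0.1)
    h <- set_fam(h, paste0("phi4.", g), -0.2, -0.1)
  }
  h <- set_fam(h, "phi5.backpack_EF", 0.2, 0.3)
  h <- set_fam(h, "phi5.boat_EF", -0.2, 0.0)
  h <- set_fam(h, "phi5.seine_LM", -0.1, 0.0)
  h <- set_fam(h, "phi5.seine_SM", -0.1, 0.0)
  h <- set_fam(h, "phi6.backpack_EF", 0.2, 0.0)
  h <- set_fam(h, "phi6.boat_EF", 0.2, 0.0)
  out <- list(hyper = h, sigma_pool = 0.5, sigma_time = 0.3,
              upsilon = stats::setNames(c(0.8, 0.6, 0.9, 0.9),
                                        pf_gears()),
              lm_scalar = 0.6)
  over <- list(...)
  stopifnot(all(names(over) %in% names(out)))
  out[names(over)] <- over
  out
}

# study-design constants of the emulated survey
design_constants <- function(preset) {
  base <- list(
    depth_range_mc = c(0.35, 4.8), depth_range_fp = c(0.1, 3.5),
    turbidity_meanlog = log(15), turbidity_sdlog = 1,
    complexity_range = c(0, 80), river_km_range = c(0, 300),
    conductivity_meanlog = log(300), conductivity_sdlog = 0.5,
    effort_ef_range = c(100, 1200), effort_seine_range = c(5, 60),
    lm_10m_prob = 0.7, boat_min_depth = 1.0,
    length_range_mm = c(25, 600))
  pre <- switch(preset,
    fitzroy_like = list(n_species = 21, n_pools_mc = 20, n_pools_fp = 39,
                        n_visits = 107, years = 2018:2021,
                        samples_per_visit = c(2, 18)),
    fitzroy_small = list(n_species = 12, n_pools_mc = 10, n_pools_fp = 20,
                         n_visits = 30, years = 2018,
                         samples_per_visit = c(6, 6)),
    tiny = list(n_species = 2, n_pools_mc = 2, n_pools_fp = 1,
                n_visits = 3, years = 2018,
                samples_per_visit = c(2, 2)),
    stop("unknown preset: ", preset))
  c(base, pre)
}

#' Realize a synthetic survey design
#'
#' Builds the species, pool, visit and sample tables of a synthetic
#' survey emulating the study design the model targets: pools split
#' between main channel and floodplain with mesohabitat-specific depth
#' ranges, repeat visits across years, a variable number of spatially
#' distinct samples per visit, and gear allocation that respects field
#' practice (boat electrofishing only where the sample is deeper than
#' 1 m, backpack electrofishing in shallow water, both seines across the
#' depth range, large-mesh seine hauled as a 10-m net with probability
#' 0.7 and a 5-m net otherwise).
#'
#' @param preset `"fitzroy_like"` (21 species, 20 main-channel + 39
#'   floodplain pools, 107 site-visits over 4 years, 2--18 samples per
#'   visit), `"fitzroy_small"` (12 species, 30 pools, 1 visit each, 6
#'   samples) or `"tiny"` (2 species, 3 pools, 2 samples).
#' @param seed Integer seed; the realized design is deterministic given
#'   the preset and seed.
#' @return An (unscaled) `survey_dataset` without detections; the design
#'   constants are attached as attribute `"design"`.
#' @export
make_design <- function(preset = c("fitzroy_like", "fitzroy_small",
                                   "tiny"), seed = 1) {
  preset <- match.arg(preset)
  dc <- design_constants(preset)
  set.seed(seed)

  # species span a length gradient (geometric spacing, mm)
  S <- dc$n_species
  len <- exp(seq(log(dc$length_range_mm[1]), log(dc$length_range_mm[2]),
                 length.out = S))
  species <- data.frame(
    species_id = sprintf("sp%02d", seq_len(S)),
    mean_length = round(len, 1), stringsAsFactors = FALSE)

  n_pools <- dc$n_pools_mc + dc$n_pools_fp
  meso <- rep(c(0L, 1L), c(dc$n_pools_mc, dc$n_pools_fp))
  depth <- ifelse(meso == 0,
                  runif(n_pools, dc$depth_range_mc[1], dc$depth_range_mc[2]),
                  runif(n_pools, dc$depth_range_fp[1], dc$depth_range_fp[2]))
  pools <- data.frame(
    pool_id = sprintf("pool%02d", seq_len(n_pools)),
    mesohabitat = meso,
    max_depth = round(depth, 3),
    turbidity = round(rlnorm(n_pools, dc$turbidity_meanlog,
                             dc$turbidity_sdlog), 2),
    complexity = round(runif(n_pools, dc$complexity_range[1],
                             dc$complexity_range[2]), 1),
    river_km = round(runif(n_pools, dc$river_km_range[1],
                           dc$river_km_range[2]), 1),
    conductivity = round(rlnorm(n_pools, dc$conductivity_meanlog,
                                dc$conductivity_sdlog), 1),
    stringsAsFactors = FALSE)

  # every pool visited once; remaining site-visits are extra pool x year
  # combinations sampled without replacement
  combos <- expand.grid(pool = seq_len(n_pools), year = dc$years)
  first <- vapply(seq_len(n_pools), function(p) {
    idx <- which(combos$pool == p)
    idx[sample.int(length(idx), 1)]
  }, integer(1))
  extra_n <- dc$n_visits - n_pools
  if (extra_n < 0) stop("preset has fewer visits than pools")
  pool_extra <- setdiff(seq_len(nrow(combos)), first)
  extra <- if (extra_n > 0) sample(pool_extra, extra_n) else integer(0)
  chosen <- combos[sort(c(first, extra)), ]
  visits <- data.frame(
    visit_id = sprintf("v%03d", seq_len(nrow(chosen))),
    pool_id = pools$pool_id[chosen$pool],
    year = as.integer(chosen$year), stringsAsFactors = FALSE)

  # samples: depth within the pool, gear respecting the depth rule
  samp <- do.call(rbind, lapply(seq_len(nrow(visits)), function(v) {
    pd <- pools$max_depth[match(visits$pool_id[v], pools$pool_id)]
    n_k <- if (dc$samples_per_visit[1] == dc$samples_per_visit[2])
      dc$samples_per_visit[1] else
        sample(dc$samples_per_visit[1]:dc$samples_per_visit[2], 1)
    sd_k <- round(runif(n_k, min(0.05, pd * 0.5), pd), 3)
    gear <- vapply(sd_k, function(d) {
      opts <- if (d > dc$boat_min_depth)
        c("boat_EF", "seine_LM", "seine_SM") else
          c("backpack_EF", "seine_LM", "seine_SM")
      sample(opts, 1)
    }, character(1))
    variant <- ifelse(gear != "seine_LM", "none",
                      ifelse(runif(n_k) < dc$lm_10m_prob,
                             "seine10m", "seine5m"))
    effort <- ifelse(gear %in% pf_ef_gears(),
                     round(runif(n_k, dc$effort_ef_range[1],
                                 dc$effort_ef_range[2])),
                     round(runif(n_k, dc$effort_seine_range[1],
                                 dc$effort_seine_range[2]), 1))
    data.frame(visit_id = visits$visit_id[v], gear = gear,
               effort_raw = effort, sample_depth = sd_k,
               sample_complexity = round(runif(n_k, 0, 80), 1),
               seine_variant = variant, stringsAsFactors = FALSE)
  }))
  samp <- data.frame(sample_id = sprintf("s%04d", seq_len(nrow(samp))),
                     samp, stringsAsFactors = FALSE)

  ds <- survey_dataset(species, pools, visits, samp)
  attr(ds, "design") <- dc
  ds
}

#' Draw species-level truth parameters from the hierarchy
#'
#' Species coefficients are drawn from their fourth-corner distributions
#' \eqn{N(\eta_{1,s} + \eta_{2,s} L_i, \sigma_s^2)}, random effects from
#' \eqn{N(0, \sigma^2)}, and the effort exponents and 5-m seine scalar
#' are taken from the hyperparameter preset. With `sigma = 0` in a
#' family the coefficients equal the length-explained mean exactly.
#'
#' @param dataset A scaled `survey_dataset` (species lengths define the
#'   coefficient means).
#' @param hyper Generating hyperparameters, see [default_truth_hyper()].
#' @param seed Integer seed.
#' @return A `pf_params` truth parameter set.
#' @export
draw_parameters <- function(dataset, hyper = default_truth_hyper(),
                            seed = 1) {
  if (is.null(dataset$species$length_std))
    stop("dataset must be scaled (species length standardized)")
  if (any(hyper$hyper$sigma < 0)) stop("family sigma must be >= 0")
  if (hyper$sigma_pool <= 0 || hyper$sigma_time <= 0)
    stop("random-effect sigmas must be > 0")
  set.seed(seed)
  p <- params_template(dataset)
  L <- dataset$species$length_std
  h <- hyper$hyper[match(pf_families(), hyper$hyper$family), ]
  for (s in seq_len(nrow(h))) {
    mu <- h$eta1[s] + h$eta2[s] * L
    draw <- rnorm(length(L), mu, h$sigma[s])
    f <- h$family[s]
    if (grepl("^beta", f)) {
      p$beta[, as.integer(sub("beta", "", f))] <- draw
    } else {
      parts <- strsplit(sub("^phi", "", f), ".", fixed = TRUE)[[1]]
      p$phi[[parts[2]]][, as.integer(parts[1])] <- draw
    }
  }
  p$hyper <- h[, c("family", "eta1", "eta2", "sigma")]
  rownames(p$hyper) <- NULL
  p$eps_pool[] <- rnorm(length(p$eps_pool), 0, hyper$sigma_pool)
  p$eps_time[] <- rnorm(length(p$eps_time), 0, hyper$sigma_time)
  p$sigma_pool <- hyper$sigma_pool
  p$sigma_time <- hyper$sigma_time
  p$upsilon[] <- hyper$upsilon[pf_gears()]
  p$lm_scalar <- hyper$lm_scalar
  p
}

# one stochastic pass of the generative chain given latent state
simulate_detections_from_state <- function(state, dataset) {
  S <- nrow(dataset$species); J <- nrow(dataset$visits)
  sa <- dataset$samples
  visit_of <- match(sa$visit_id, dataset$visits$visit_id)
  N <- matrix(rpois(S * J, state$lambda), S, J,
              dimnames = dimnames(state$lambda))
  Kmax <- if (nrow(sa)) max(sa$k) else 0L
  y <- array(NA_integer_, c(S, J, Kmax),
             dimnames = list(dataset$species$species_id,
                             dataset$visits$visit_id, NULL))
  p <- matrix(0, S, nrow(sa), dimnames = dimnames(state$r))
  for (n in seq_len(nrow(sa))) {
    j <- visit_of[n]
    p[, n] <- detection_prob(pmin(pmax(state$r[, n], 0), 1), N[, j])
    y[, j, sa$k[n]] <- rbinom(S, 1, p[, n])
  }
  list(N = N, p = p, y = y)
}

#' Simulate a survey from the generative model
#'
#' Runs the full generative chain on a realized design: expected
#' abundance from the Ricker abundance sub-model, latent abundance
#' \eqn{N \sim Poisson(\lambda)}, capture probability from the gear
#' observation sub-models, and detections
#' \eqn{y \sim Bernoulli(1-(1-r)^N)}. The generating truth (parameters
#' and latent states) is attached so fits can be scored against it; use
#' [write_survey()] to emit blinded tables.
#'
#' @param design A `survey_dataset` from [make_design()] (scaled
#'   automatically if needed).
#' @param truth A `pf_params` truth set from [draw_parameters()]; by
#'   default drawn from [default_truth_hyper()] with `seed`.
#' @param seed Integer seed for the stochastic chain.
#' @return The dataset with detections and a `truth` bundle (`params`,
#'   `lambda`, `N`, `r`, `p`).
#' @export
simulate_survey <- function(design, truth = NULL, seed = 1) {
  stopifnot(inherits(design, "survey_dataset"))
  if (is.null(design$scaling)) design <- scale_covariates(design)
  if (is.null(truth)) truth <- draw_parameters(design, seed = seed)
  state <- latent_state(truth, design)
  set.seed(seed)
  sim <- simulate_detections_from_state(state, design)
  design$y <- validate_detection_array(sim$y, design$species,
                                       design$visits, design$samples)
  design$truth <- list(params = truth, lambda = state$lambda,
                       N = sim$N, r = state$r, p = sim$p)
  design
}
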