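#' Default priors and regularization
#'
#' Mildly informative priors with mild regularization through the trait
#' hierarchy: the species-coefficient families are shrunk toward their
#' length-explained means by a Half-Normal(0.5) prior on each family
#' spread \eqn{\sigma_s}, which is the fourth-corner penalty. Family
#' intercepts get Normal(0, 2^2), length slopes Normal(0, 1^2),
#' random-effect spreads Half-Normal(1), and the effort exponents and 5-m
#' seine scalar Uniform(0, 1). All values are overridable and recorded in
#' the fit output.
#'
#' @param dataset A `survey_dataset` (defines the 32 coefficient
#'   families).
#' @param ... Overrides for any element of the returned list.
#' @return Object of class `pf_priors`: list with `eta1_sd`, `eta2_sd`,
#'   `sigma_s_scale`, `sigma_pool_scale`, `sigma_time_scale`,
#'   `upsilon_bounds`, `lm_scalar_bounds`, plus the family table
#'   (`families`).
#' @export
default_priors <- function(dataset, ...) {
  pr <- list(eta1_sd = 2, eta2_sd = 1, sigma_s_scale = 0.5,
             sigma_pool_scale = 1, sigma_time_scale = 1,
             upsilon_bounds = c(0, 1), lm_scalar_bounds = c(0, 1),
             families = pf_families())
  over <- list(...)
  stopifnot(all(names(over) %in% names(pr)))
  pr[names(over)] <- over
  if (any(unlist(pr[c("eta1_sd", "eta2_sd", "sigma_s_scale",
                      "sigma_pool_scale", "sigma_time_scale")]) <= 0))
    stop("prior scales must be > 0")
  structure(pr, class = "pf_priors")
}

#' MCMC sampler configuration
#'
#' @param n_chains Number of chains (>= 2; the default mirrors the
#'   four-chain fitting protocol).
#' @param n_warmup Adaptation iterations discarded per chain.
#' @param n_draws Retained draws per chain.
#' @param thin Keep every `thin`-th post-warmup sweep.
#' @param seed Integer seed; fixed and recorded.
#' @param init_jitter SD of the per-chain jitter on initial values.
#' @param rhat_max,ess_min Convergence targets: the fit warns (does not
#'   fail) when any split R-hat exceeds `rhat_max` or any ESS falls below
#'   `ess_min`.
#' @param gibbs_hyper Use exact conjugate Gibbs draws for the
#'   fourth-corner (eta1, eta2) pairs (default); `FALSE` switches them to
#'   Metropolis updates (the two samplers target the same posterior).
#' @param nmax_tail,nmax_floor,nmax_cap Truncation control for the
#'   latent-abundance sum (see [n_max_adaptive()]).
#' @param am_reps,seesaw_reps Per-sweep repetition counts of the two
#'   block moves that traverse the posterior's stiff directions (the
#'   adaptive family-hyperparameter move and the
#'   abundance-vs-catchability see-saw). The defaults suit long
#'   diagnostic-grade fits; short exploratory fits can lower them.
#' @return Object of class `pf_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_warmup = 1000, n_draws = 1000,
                        thin = 1, seed = 1, init_jitter = 0.1,
                        rhat_max = 1.1, ess_min = 400,
                        gibbs_hyper = TRUE, nmax_tail = 1e-10,
                        nmax_floor = 50, nmax_cap = 5000,
                        am_reps = 32, seesaw_reps = 12) {
  if (n_chains < 2) stop("n_chains must be >= 2")
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_draws = as.integer(n_draws), thin = as.integer(thin),
                 seed = as.integer(seed), init_jitter = init_jitter,
                 rhat_max = rhat_max, ess_min = ess_min,
                 gibbs_hyper = gibbs_hyper, nmax_tail = nmax_tail,
                 nmax_floor = as.integer(nmax_floor),
                 nmax_cap = as.integer(nmax_cap),
                 am_reps = as.integer(am_reps),
                 seesaw_reps = as.integer(seesaw_reps)),
            class = "pf_mcmc_config")
}

# flatten a scaled survey_dataset into the arrays the compiled core uses
model_data_list <- function(dataset) {
  if (is.null(dataset$scaling))
    stop("dataset must be scaled (scale_covariates) before fitting")
  if (is.null(dataset$y)) stop("dataset has no detection array")
  po <- dataset$pools; vi <- dataset$visits; sa <- dataset$samples
  years <- sort(unique(vi$year))
  pool_of <- match(vi$pool_id, po$pool_id)
  visit_of <- match(sa$visit_id, vi$visit_id)
  cond <- po$conductivity_s
  cond[is.na(cond)] <- 0  # only read for electrofishing samples
  S <- nrow(dataset$species)
  ymat <- matrix(0L, S, nrow(sa))
  jk <- cbind(visit_of, sa$k)
  for (i in seq_len(S)) ymat[i, ] <- dataset$y[cbind(i, jk)]
  list(S = S, J = nrow(vi), P = nrow(po), Ny = length(years),
       visit_pool = pool_of - 1L,
       visit_year = match(vi$year, years) - 1L,
       vD = po$depth_s[pool_of], vM = as.double(po$mesohabitat[pool_of]),
       vT = po$turbidity_s[pool_of], vS = po$complexity_s[pool_of],
       vR = po$river_km_s[pool_of],
       samp_visit = visit_of - 1L,
       samp_gear = match(sa$gear, pf_gears()) - 1L,
       samp_is5m = as.integer(sa$seine_variant == "seine5m"),
       samp_E = sa$effort_s, samp_Dk = sa$sample_depth_s,
       samp_T = po$turbidity_s[pool_of][visit_of],
       samp_Sk = sa$sample_complexity_s,
       samp_C = cond[pool_of][visit_of],
       y = ymat, L = dataset$species$length_std,
       years = years)
}

# pf_params -> the flat containers the compiled core uses
params_to_cpp <- function(params) {
  list(beta = unname(params$beta),
       phi = unname(do.call(cbind, params$phi[pf_gears()])),
       eta1 = params$hyper$eta1, eta2 = params$hyper$eta2,
       sigma = params$hyper$sigma,
       eps_pool = unname(params$eps_pool),
       eps_time = unname(params$eps_time),
       sigma_pool = params$sigma_pool, sigma_time = params$sigma_time,
       upsilon = unname(params$upsilon), lm_scalar = params$lm_scalar)
}

cpp_control <- function(config, n_warmup = NULL, n_draws = NULL) {
  list(n_warmup = if (is.null(n_warmup)) config$n_warmup else n_warmup,
       n_draws = if (is.null(n_draws)) config$n_draws else n_draws,
       thin = config$thin, gibbs_hyper = config$gibbs_hyper,
       nmax_tail = config$nmax_tail, nmax_floor = config$nmax_floor,
       nmax_cap = config$nmax_cap,
       am_reps = if (is.null(config$am_reps)) 32L else config$am_reps,
       seesaw_reps = if (is.null(config$seesaw_reps)) 12L else
         config$seesaw_reps)
}

# initial state: hierarchy means at zero, spreads at 0.3, upsilon at 0.5,
# lm scalar at 0.8, random effects at zero; jittered per chain
initial_params <- function(dataset, jitter = 0.1) {
  p <- params_template(dataset)
  S <- nrow(p$beta)
  p$beta <- p$beta + matrix(rnorm(S * 10, 0, jitter), S, 10)
  for (g in pf_gears())
    p$phi[[g]] <- p$phi[[g]] +
      matrix(rnorm(length(p$phi[[g]]), 0, jitter), S)
  p$hyper$eta1 <- rnorm(nrow(p$hyper), 0, jitter)
  p$hyper$eta2 <- rnorm(nrow(p$hyper), 0, jitter)
  p$hyper$sigma <- p$hyper$sigma * exp(rnorm(nrow(p$hyper), 0, jitter))
  p$upsilon[] <- plogis(qlogis(p$upsilon) + rnorm(4, 0, jitter))
  p$lm_scalar <- plogis(qlogis(p$lm_scalar) + rnorm(1, 0, jitter))
  p
}

#' Sample the posterior of the full model
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler on the marginalized
#' posterior: componentwise adaptive random-walk updates for species
#' coefficients, random effects, spreads (log scale) and the bounded
#' effort/seine parameters (logit scale, with Jacobians), and exact
#' conjugate Gibbs draws for the fourth-corner intercept/slope pairs.
#' Chains run sequentially from a single RNG stream seeded by
#' `config$seed`, so results are bit-reproducible.
#'
#' @param dataset A filtered, scaled `survey_dataset` with detections.
#' @param priors A `pf_priors` object; default [default_priors()].
#' @param config A `pf_mcmc_config`; default [mcmc_config()].
#' @return Object of class `pf_posterior`: list with `draws` (list of
#'   draw x parameter matrices, one per chain, natural scale), `lp`
#'   (matching joint log-posterior values), `par_names`, `diagnostics`
#'   (per-parameter split R-hat, ESS, mean, sd, quantiles), `config`,
#'   `priors`, and the `dataset`. Warns (never fails) when diagnostics
#'   miss the configured targets.
#' @export
run_mcmc <- function(dataset, priors = default_priors(dataset),
                     config = mcmc_config()) {
  data <- model_data_list(dataset)
  par_names <- names(flatten_params(params_template(dataset)))
  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  lp <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    init <- initial_params(dataset, config$init_jitter)
    lp0 <- cpp_log_posterior(data, params_to_cpp(init),
                             unclass(priors), cpp_control(config))
    if (!is.finite(lp0))
      stop("non-finite initial log-posterior")
    res <- cpp_run_chain(data, params_to_cpp(init), unclass(priors),
                         cpp_control(config))
    colnames(res$draws) <- par_names
    chains[[ch]] <- res$draws
    lp[[ch]] <- res$lp
  }
  diag <- posterior_diagnostics(chains)
  out <- structure(list(draws = chains,
                        lp = do.call(cbind, lp),
                        par_names = par_names,
                        diagnostics = diag,
                        config = config, priors = priors,
                        dataset = dataset),
                   class = "pf_posterior")
  bad_rhat <- diag$rhat > config$rhat_max
  bad_ess <- diag$ess < config$ess_min
  if (any(bad_rhat, na.rm = TRUE))
    warning(sum(bad_rhat, na.rm = TRUE), " parameter(s) with split ",
            "R-hat > ", config$rhat_max, call. = FALSE)
  if (any(bad_ess, na.rm = TRUE))
    warning(sum(bad_ess, na.rm = TRUE), " parameter(s) with ESS < ",
            config$ess_min, call. = FALSE)
  out
}

#' @export
print.pf_posterior <- function(x, ...) {
  nd <- nrow(x$draws[[1]])
  cat("pf_posterior:", length(x$draws), "chains x", nd, "draws,",
      length(x$par_names), "parameters\n")
  cat("  max split R-hat:",
      format(max(x$diagnostics$rhat, na.rm = TRUE), digits = 4),
      "| min ESS:",
      format(min(x$diagnostics$ess, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Stack posterior chains into a single draw matrix
#'
#' @param posterior A `pf_posterior`.
#' @return Matrix (all draws x parameters).
#' @export
posterior_matrix <- function(posterior) {
  do.call(rbind, posterior$draws)
}

#' Per-parameter summary and convergence table for a set of chains
#'
#' @param chains List of draw x parameter matrices (same columns).
#' @return data.frame with parameter, mean, sd, 5/50/95% quantiles,
#'   split R-hat and ESS.
#' @export
posterior_diagnostics <- function(chains) {
  pn <- colnames(chains[[1]])
  all <- do.call(rbind, chains)
  out <- data.frame(parameter = pn,
                    mean = colMeans(all),
                    sd = apply(all, 2, sd),
                    q05 = apply(all, 2, quantile, 0.05),
                    q50 = apply(all, 2, quantile, 0.50),
                    q95 = apply(all, 2, quantile, 0.95),
                    rhat = NA_real_, ess = NA_real_,
                    row.names = NULL)
  for (p in seq_along(pn)) {
    m <- sapply(chains, function(d) d[, p])
    out$rhat[p] <- rhat(m)
    out$ess[p] <- ess(m)
  }
  out
}

# split columns (chains) of a draw matrix into first/second halves
split_chains <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Gelman--Rubin diagnostic on split chains: each chain is halved, and
#' the ratio of pooled to within-chain variance is computed over the
#' resulting 2m sequences. Values near 1 indicate the chains agree;
#' values above ~1.1 flag non-convergence. Degenerate (zero-variance)
#' chains give `NA`.
#'
#' @param x Draws: a matrix with one column per chain, or a list of
#'   per-chain vectors. At least 2 chains of at least 4 draws.
#' @return Split R-hat (scalar), or `NA` if undefined.
#' @export
rhat <- function(x) {
  s <- split_chains(x)
  n <- nrow(s); m <- ncol(s)
  if (m < 4 || n < 2) stop("need >= 2 chains of >= 4 draws")
  W <- mean(apply(s, 2, var))
  B <- n * var(colMeans(s))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# FFT autocovariance of a demeaned sequence (biased, divisor n)
autocov_fft <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  nf <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(v, rep(0, nf - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[1:n] / nf / n
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based multi-chain ESS: combined autocorrelations are
#' estimated from the split chains, summed with Geyer's initial monotone
#' positive-pair sequence, and the total draw count is deflated by the
#' resulting integrated autocorrelation time. Degenerate (zero-variance)
#' chains give `NA`.
#'
#' @inheritParams rhat
#' @return Estimated effective sample size, or `NA` if undefined.
#' @export
ess <- function(x) {
  s <- split_chains(x)
  n <- nrow(s); m <- ncol(s)
  if (m < 4 || n < 2) stop("need >= 2 chains of >= 4 draws")
  W <- mean(apply(s, 2, var))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- n * var(colMeans(s))
  var_plus <- (n - 1) / n * W + B / n
  acov <- sapply(seq_len(m), function(c) autocov_fft(s[, c]))
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # lags 0 .. n-1
  # Geyer initial monotone positive sequence over lag pairs:
  # tau = -rho_0 + 2 * sum of positive, non-increasing pair sums
  prev <- Inf
  t <- 1
  total <- 0
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair <= 0) break
    pair <- min(pair, prev)
    prev <- pair
    total <- total + pair
    t <- t + 2
  }
  tau_int <- max(2 * total - rho[1], rho[1], 1e-12)
  max(1, m * n / tau_int)
}

#' Write posterior draws and diagnostics as delimited tables
#'
#' Writes `draws.csv` (chain, draw, one column per parameter, natural
#' scale), `diagnostics.csv`, the sampler configuration and priors as
#' `fit_meta.csv`, and the frozen covariate scaling as `scaling.csv`.
#'
#' @param posterior A `pf_posterior`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(posterior, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dr <- do.call(rbind, lapply(seq_along(posterior$draws), function(ch)
    data.frame(chain = ch, draw = seq_len(nrow(posterior$draws[[ch]])),
               posterior$draws[[ch]], check.names = FALSE)))
  write.csv(dr, file.path(path, "draws.csv"), row.names = FALSE)
  write.csv(posterior$diagnostics, file.path(path, "diagnostics.csv"),
            row.names = FALSE)
  cfg <- posterior$config; pr <- posterior$priors
  meta <- data.frame(
    name = c(names(unlist(cfg)), paste0("prior.",
             names(unlist(pr[setdiff(names(pr), "families")])))),
    value = c(unlist(cfg), unlist(pr[setdiff(names(pr), "families")])))
  write.csv(meta, file.path(path, "fit_meta.csv"), row.names = FALSE)
  ds <- posterior$dataset
  if (!is.null(ds$scaling)) {
    sc <- ds$scaling
    flat <- data.frame(name = c("depth_divisor", "sample_depth_divisor",
                                paste0("effort_divisor.", pf_gears()),
                                "turbidity_center", "turbidity_sd",
                                "complexity_center", "complexity_sd",
                                "river_km_center", "river_km_sd",
                                "conductivity_center", "conductivity_sd",
                                "length_center", "length_sd"),
                       value = c(sc$depth_divisor,
                                 sc$sample_depth_divisor,
                                 sc$effort_divisor, sc$turbidity_center,
                                 sc$turbidity_sd, sc$complexity_center,
                                 sc$complexity_sd, sc$river_km_center,
                                 sc$river_km_sd, sc$conductivity_center,
                                 sc$conductivity_sd, sc$length_center,
                                 sc$length_sd))
    write.csv(flat, file.path(path, "scaling.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Extract one posterior draw as a parameter set
#'
#' @param posterior A `pf_posterior`.
#' @param chain,draw Chain and draw indices.
#' @return A `pf_params` object.
#' @export
posterior_params <- function(posterior, chain = 1, draw = 1) {
  unflatten_params(posterior$draws[[chain]][draw, ], posterior$dataset)
}
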