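#' Log expected abundance of a species across pools (Ricker depth response)
#'
#' The abundance linear predictor on the log scale:
#' \deqn{\log\lambda = (\beta_1+\beta_3 M) + \log D - e^{\beta_2+\beta_4 M} D
#'   + \beta_5 T + \beta_6 T M + \beta_7 S + \beta_8 S M
#'   + \beta_9 R + \beta_{10} R M + \epsilon^{pool} + \epsilon^{time}.}
#' The \eqn{\log D - e^{\cdot} D} pair is a Ricker response in scaled
#' depth \eqn{D \in (0,1]}: abundance is zero in a dry pool, rises with
#' depth and declines past an interior optimum (or increases monotonically
#' over the observed range when the optimum sits beyond the deepest pool).
#' At \eqn{D = 0} the expected abundance is defined as exactly 0 (the
#' continuity limit), so drawn-down scenario depths of zero are legal.
#'
#' @param beta_i Numeric vector of 10 abundance coefficients for one
#'   species.
#' @param pool_covariates data.frame/list with elements `depth_s` (scaled
#'   depth, in \[0,1\]), `mesohabitat` (0/1), `turbidity_s`,
#'   `complexity_s`, `river_km_s` (standardized).
#' @param eps_pool,eps_time Random-effect values (scalar or per pool).
#' @return Numeric vector of \eqn{\log\lambda} per pool (`-Inf` where
#'   depth is 0).
#' @export
abundance_linpred <- function(beta_i, pool_covariates, eps_pool = 0,
                              eps_time = 0) {
  stopifnot(length(beta_i) == 10)
  pc <- pool_covariates
  D <- pc$depth_s
  if (any(D < 0)) stop("scaled depth must be >= 0")
  M <- pc$mesohabitat
  logD <- ifelse(D > 0, log(D), -Inf)
  logD + (beta_i[1] + beta_i[3] * M) -
    exp(beta_i[2] + beta_i[4] * M) * D +
    beta_i[5] * pc$turbidity_s + beta_i[6] * pc$turbidity_s * M +
    beta_i[7] * pc$complexity_s + beta_i[8] * pc$complexity_s * M +
    beta_i[9] * pc$river_km_s + beta_i[10] * pc$river_km_s * M +
    eps_pool + eps_time
}

#' Depth at which expected abundance peaks
#'
#' The Ricker term \eqn{\log D - e^{\beta_2+\beta_4 M} D} is maximized at
#' \eqn{D^* = e^{-(\beta_2+\beta_4 M)}} (scaled depth). Values above 1
#' mean abundance increases monotonically over the observed depth range.
#'
#' @param beta2,beta4 Ricker log-decay coefficient and its floodplain
#'   offset.
#' @param M Mesohabitat indicator (0 main channel, 1 floodplain).
#' @return Scaled optimal depth \eqn{D^*}.
#' @export
peak_depth <- function(beta2, beta4 = 0, M = 0) {
  exp(-(beta2 + beta4 * M))
}

#' Log catchability of a species in a set of samples
#'
#' The gear-specific observation linear predictor
#' \deqn{\log q = \phi_1 + \log \acute D - e^{\phi_2}\acute D + \phi_3 T +
#'   \phi_4 T^2 + \phi_5 \acute S \,[+\, \phi_6 C],}
#' with a Ricker response in scaled sample depth \eqn{\acute D}, a
#' quadratic pool-turbidity effect, a sample-complexity effect and, for
#' the electrofishing gears only, a pool-conductivity effect.
#'
#' @param phi_i Numeric vector of catchability coefficients for one
#'   species: length 6 for electrofishing gears, 5 for seines.
#' @param sample_covariates data.frame/list with `sample_depth_s` (scaled,
#'   (0,1\]), `turbidity_s`, `sample_complexity_s` and, for
#'   electrofishing, `conductivity_s` (all standardized; turbidity and
#'   conductivity are pool-scale values).
#' @param gear One of [pf_gears()].
#' @return Numeric vector of \eqn{\log q} per sample.
#' @export
catchability_linpred <- function(phi_i, sample_covariates, gear) {
  gear <- match.arg(gear, pf_gears())
  np <- pf_n_phi()[[gear]]
  if (length(phi_i) != np)
    stop("phi_i must have length ", np, " for gear ", gear)
  sc <- sample_covariates
  is_ef <- gear %in% pf_ef_gears()
  if (!is_ef && !is.null(sc$conductivity_s) &&
      any(sc$conductivity_s != 0, na.rm = TRUE))
    stop("conductivity is modelled only for electrofishing gears")
  Dk <- sc$sample_depth_s
  if (any(Dk <= 0)) stop("scaled sample depth must be > 0")
  out <- phi_i[1] + log(Dk) - exp(phi_i[2]) * Dk +
    phi_i[3] * sc$turbidity_s + phi_i[4] * sc$turbidity_s^2 +
    phi_i[5] * sc$sample_complexity_s
  if (is_ef) out <- out + phi_i[6] * sc$conductivity_s
  out
}

#' Capture probability from catchability and effort
#'
#' Effort scales catchability into the per-sample capture probability
#' \deqn{r = \varsigma\, E^{\upsilon} (1 - e^{-q}), \quad q = e^{\log q},}
#' with scaled effort \eqn{E \in (0,1]} and shape \eqn{\upsilon \in
#' [0,1]}: \eqn{\upsilon = 1} is a proportional effort relationship,
#' values below 1 saturate, and \eqn{\upsilon = 0} removes the effort
#' dependence. \eqn{\varsigma \in (0,1]} is the 5-m large-mesh seine
#' multiplier (1 for every other sample).
#'
#' @param log_q Log catchability (vector).
#' @param effort_s Scaled effort in \[0,1\] (0 only as a simulation
#'   limit, giving r = 0 when `upsilon > 0`).
#' @param upsilon Effort exponent in \[0,1\].
#' @param lm_scalar The 5-m seine multiplier \eqn{\varsigma} in (0,1\].
#' @return Capture probabilities in \[0,1\].
#' @export
capture_prob <- function(log_q, effort_s, upsilon, lm_scalar = 1) {
  if (any(effort_s < 0)) stop("scaled effort must be >= 0")
  if (any(upsilon < 0 | upsilon > 1)) stop("upsilon must be in [0,1]")
  if (any(lm_scalar <= 0 | lm_scalar > 1))
    stop("lm_scalar must be in (0,1]")
  lm_scalar * effort_s^upsilon * (-expm1(-exp(log_q)))
}

#' Detection probability given latent abundance
#'
#' The probability of catching at least one of \eqn{N} independent
#' individuals when each is caught with probability \eqn{r}:
#' \eqn{p = 1 - (1-r)^N}, evaluated as \eqn{-expm1(N \log(1-r))} for
#' numerical stability; \eqn{p = 0} whenever \eqn{N = 0}.
#'
#' @param r Capture probability in \[0,1\].
#' @param N Non-negative integer abundance.
#' @return Detection probability in \[0,1\].
#' @export
detection_prob <- function(r, N) {
  if (any(r < 0 | r > 1)) stop("r must be in [0,1]")
  if (any(N < 0)) stop("N must be >= 0")
  rc <- pmin(r, 1 - 1e-12)
  out <- -expm1(N * log1p(-rc))
  out[N == 0] <- 0
  out[r == 1 & N >= 1] <- 1
  out
}

#' Adaptive truncation point for the latent-abundance sum
#'
#' Smallest N whose Poisson CDF reaches `1 - tail`, floored at `n_min`
#' and capped at `n_cap`; beyond it the neglected Poisson tail mass is
#' below `tail`.
#'
#' @param lambda Expected abundance (vectorized).
#' @param tail Neglected tail mass (default 1e-10).
#' @param n_min,n_cap Floor (50) and cap (5000) on the truncation point.
#' @return Integer truncation point(s).
#' @export
n_max_adaptive <- function(lambda, tail = 1e-10, n_min = 50L,
                           n_cap = 5000L) {
  pmin(pmax(qpois(tail, lambda, lower.tail = FALSE), n_min), n_cap)
}

#' Marginal log-likelihood of one species x site-visit detection history
#'
#' The Poisson--Bernoulli mixture marginalized over latent abundance:
#' \deqn{\log \sum_{N=0}^{N_{max}} Pois(N \mid \lambda)
#'   \prod_k p_k(N)^{y_k} (1-p_k(N))^{1-y_k},}
#' with \eqn{p_k(N) = 1-(1-r_k)^N}, evaluated in log space with a
#' log-sum-exp. Marginalizing replaces latent-abundance augmentation:
#' the model content is unchanged but the likelihood becomes a
#' deterministic scalar that generic samplers (and brute-force oracles)
#' can evaluate directly.
#'
#' @param lambda Expected abundance (scalar, >= 0).
#' @param r Capture probabilities of the visit's samples (vector in
#'   \[0,1\]).
#' @param y Detection history (0/1 vector, same length as `r`).
#' @param N_max Optional fixed truncation; default adaptive via
#'   [n_max_adaptive()].
#' @return Log-likelihood (scalar; `-Inf` when a detection is impossible,
#'   e.g. \eqn{\lambda = 0} with a positive `y`).
#' @export
marginal_loglik_unit <- function(lambda, r, y, N_max = NULL) {
  stopifnot(length(r) == length(y), lambda >= 0,
            all(y %in% c(0, 1)), all(r >= 0 & r <= 1))
  if (lambda == 0) return(if (any(y == 1)) -Inf else 0)
  if (is.null(N_max)) N_max <- n_max_adaptive(lambda)
  N <- 0:N_max
  l1mr <- log1p(-pmin(r, 1 - 1e-12))           # log(1-r), length K
  logS <- outer(N, l1mr)                       # log(1-p_k(N))
  obs <- y == 1
  contrib <- numeric(length(N))
  if (any(obs)) {
    logp <- log(-expm1(logS[, obs, drop = FALSE]))
    contrib <- contrib + rowSums(logp)
  }
  if (any(!obs))
    contrib <- contrib + rowSums(logS[, !obs, drop = FALSE])
  terms <- dpois(N, lambda, log = TRUE) + contrib
  m <- max(terms)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(terms - m)))
}

#' Fourth-corner log-prior of one coefficient family
#'
#' Species coefficients in family *s* are normal random effects whose
#' mean is a linear function of standardized species mean length:
#' \eqn{coef_{s,i} \sim N(\eta_{1,s} + \eta_{2,s} L_i,\ \sigma_s^2)}.
#' This is the trait hierarchy that shares information across species and
#' regularizes species-level estimates toward the length-explained mean.
#'
#' @param coeff Species coefficient vector of the family.
#' @param eta1,eta2 Family intercept and length slope.
#' @param sigma Family spread (> 0).
#' @param length_std Standardized species mean lengths.
#' @return Summed normal log-density.
#' @export
fourth_corner_logprior <- function(coeff, eta1, eta2, sigma, length_std) {
  if (sigma <= 0) stop("sigma must be > 0")
  sum(dnorm(coeff, eta1 + eta2 * length_std, sigma, log = TRUE))
}

# fetch the species-coefficient column of a family from a pf_params
family_column <- function(params, family) {
  if (grepl("^beta", family)) {
    params$beta[, as.integer(sub("beta", "", family))]
  } else {
    parts <- strsplit(sub("^phi", "", family), ".", fixed = TRUE)[[1]]
    params$phi[[parts[2]]][, as.integer(parts[1])]
  }
}

#' Latent state implied by a parameter set on a dataset
#'
#' Computes the deterministic intermediates of the model: expected
#' abundance per species x site-visit and capture probability per species
#' x sample.
#'
#' @param params A `pf_params` object.
#' @param dataset A scaled `survey_dataset`.
#' @return List with `log_lambda` and `lambda` (species x visit
#'   matrices) and `r` (species x sample matrix, columns in samples-table
#'   order).
#' @export
latent_state <- function(params, dataset) {
  sp <- dataset$species; po <- dataset$pools
  vi <- dataset$visits; sa <- dataset$samples
  S <- nrow(sp); J <- nrow(vi); n_samp <- nrow(sa)
  pool_of <- match(vi$pool_id, po$pool_id)
  D <- po$depth_s[pool_of]; M <- po$mesohabitat[pool_of]
  Tb <- po$turbidity_s[pool_of]; Sx <- po$complexity_s[pool_of]
  R <- po$river_km_s[pool_of]
  year_of <- match(vi$year, as.integer(names(params$eps_time)))

  b <- params$beta
  lin <- b[, 1, drop = FALSE] %*% t(rep(1, J)) + outer(b[, 3], M) +
    outer(b[, 5], Tb) + outer(b[, 6], Tb * M) +
    outer(b[, 7], Sx) + outer(b[, 8], Sx * M) +
    outer(b[, 9], R) + outer(b[, 10], R * M)
  decay <- exp(outer(b[, 2], rep(1, J)) + outer(b[, 4], M))
  logD <- ifelse(D > 0, log(D), -Inf)
  log_lambda <- sweep(lin - sweep(decay, 2, D, `*`), 2, logD, `+`)
  log_lambda <- sweep(log_lambda, 2,
                      params$eps_pool[pool_of] +
                        params$eps_time[year_of], `+`)
  dimnames(log_lambda) <- list(sp$species_id, vi$visit_id)

  r <- matrix(0, S, n_samp,
              dimnames = list(sp$species_id, sa$sample_id))
  if (n_samp > 0) {
    visit_of <- match(sa$visit_id, vi$visit_id)
    Ts <- Tb[visit_of]
    Cs <- po$conductivity_s[pool_of][visit_of]
    for (g in pf_gears()) {
      idx <- which(sa$gear == g)
      if (!length(idx)) next
      ph <- params$phi[[g]]
      lq <- ph[, 1, drop = FALSE] %*% t(rep(1, length(idx))) +
        outer(rep(1, S), log(sa$sample_depth_s[idx])) -
        exp(ph[, 2]) %o% sa$sample_depth_s[idx] +
        outer(ph[, 3], Ts[idx]) + outer(ph[, 4], Ts[idx]^2) +
        outer(ph[, 5], sa$sample_complexity_s[idx])
      if (g %in% pf_ef_gears())
        lq <- lq + outer(ph[, 6], Cs[idx])
      mult <- ifelse(sa$seine_variant[idx] == "seine5m",
                     params$lm_scalar, 1)
      eff <- sa$effort_s[idx]^params$upsilon[[g]]
      r[, idx] <- sweep(-expm1(-exp(lq)), 2, mult * eff, `*`)
    }
  }
  lambda <- exp(log_lambda)
  list(log_lambda = log_lambda, lambda = lambda, r = r)
}

#' Marginal log-likelihood of a dataset under a parameter set
#'
#' Sums [marginal_loglik_unit()] over all species x site-visit detection
#' histories. This is the pure-R reference implementation; the fitting
#' engine uses an equivalent compiled version that is cross-checked
#' against this one.
#'
#' @param params A `pf_params` object.
#' @param dataset A scaled `survey_dataset` with detection array.
#' @return Total log-likelihood.
#' @export
loglik_dataset <- function(params, dataset) {
  st <- latent_state(params, dataset)
  sa <- dataset$samples
  visit_of <- match(sa$visit_id, dataset$visits$visit_id)
  total <- 0
  for (j in seq_len(nrow(dataset$visits))) {
    idx <- which(visit_of == j)
    kj <- sa$k[idx]
    for (i in seq_len(nrow(dataset$species))) {
      total <- total + marginal_loglik_unit(
        st$lambda[i, j], st$r[i, idx], dataset$y[i, j, kj])
    }
  }
  total
}

# log density of a half-normal with scale `scale`, -Inf at x <= 0
dhalfnorm_log <- function(x, scale) {
  ifelse(x > 0, log(2) + dnorm(x, 0, scale, log = TRUE), -Inf)
}

#' Joint log-posterior of the full model (natural scale)
#'
#' Assembles the marginal likelihood, the fourth-corner priors on all 32
#' coefficient families, the random-effect densities, and the
#' hyperpriors. Evaluated on the natural parameter scale (no transform
#' Jacobians; the sampler applies those internally). Non-finite or
#' out-of-support parameter values return `-Inf` rather than raising.
#'
#' @param params A `pf_params` object.
#' @param dataset A scaled `survey_dataset` (may have zero visits, giving
#'   a prior-only value).
#' @param priors A `pf_priors` object from [default_priors()].
#' @return Log-posterior density (unnormalized).
#' @export
joint_log_posterior <- function(params, dataset, priors) {
  v <- flatten_params(params)
  if (any(!is.finite(v))) return(-Inf)
  h <- params$hyper
  if (any(h$sigma <= 0) || params$sigma_pool <= 0 ||
      params$sigma_time <= 0 ||
      any(params$upsilon < 0 | params$upsilon > 1) ||
      params$lm_scalar <= 0 || params$lm_scalar > 1) return(-Inf)

  lp <- 0
  L <- dataset$species$length_std
  for (s in seq_len(nrow(h)))
    lp <- lp + fourth_corner_logprior(
      family_column(params, h$family[s]), h$eta1[s], h$eta2[s],
      h$sigma[s], L)
  lp <- lp + sum(dnorm(params$eps_pool, 0, params$sigma_pool, log = TRUE))
  lp <- lp + sum(dnorm(params$eps_time, 0, params$sigma_time, log = TRUE))
  lp <- lp + sum(dnorm(h$eta1, 0, priors$eta1_sd, log = TRUE))
  lp <- lp + sum(dnorm(h$eta2, 0, priors$eta2_sd, log = TRUE))
  lp <- lp + sum(dhalfnorm_log(h$sigma, priors$sigma_s_scale))
  lp <- lp + dhalfnorm_log(params$sigma_pool, priors$sigma_pool_scale)
  lp <- lp + dhalfnorm_log(params$sigma_time, priors$sigma_time_scale)
  # upsilon, lm_scalar: uniform(0,1) contributes 0 inside the support
  if (nrow(dataset$visits) > 0 && !is.null(dataset$y))
    lp <- lp + loglik_dataset(params, dataset)
  lp
}
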