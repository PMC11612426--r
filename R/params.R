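#' Coefficient family names of the species hierarchy
#'
#' Every species-level coefficient belongs to one of 32 families: the ten
#' abundance coefficients `beta1`..`beta10` and the per-gear catchability
#' coefficients (`phi1`..`phi6` for the electrofishing gears, which carry
#' a conductivity term, `phi1`..`phi5` for the seines). Each family has a
#' fourth-corner hierarchy (intercept `eta1`, length slope `eta2`, spread
#' `sigma`).
#'
#' @return Character vector of the 32 family labels, e.g. `"beta3"`,
#'   `"phi2.boat_EF"`.
#' @export
pf_families <- function() {
  c(paste0("beta", 1:10),
    unlist(lapply(pf_gears(), function(g)
      paste0("phi", seq_len(pf_n_phi()[[g]]), ".", g)), use.names = FALSE))
}

#' Build a zero-initialized parameter set for a dataset
#'
#' The full free-parameter set of the model: species coefficient matrices,
#' effort exponents, the 5-m seine scalar, pool and year random effects
#' with their spreads, and the 32 fourth-corner hyperparameter triples.
#'
#' @param dataset A scaled `survey_dataset` (species define the rows).
#' @return An object of class `pf_params`: list with elements `beta`
#'   (species x 10), `phi` (named list of species x 5/6 matrices per
#'   gear), `upsilon` (per gear, in \[0,1\]), `lm_scalar` (the 5-m
#'   large-mesh seine multiplier, in (0,1\]), `eps_pool`, `eps_time`,
#'   `sigma_pool`, `sigma_time`, `hyper` (data.frame family/eta1/eta2/
#'   sigma). Spreads start at 0.3, `upsilon` at 0.5, `lm_scalar` at 0.8.
#' @export
params_template <- function(dataset) {
  sp <- dataset$species$species_id
  S <- length(sp)
  years <- sort(unique(dataset$visits$year))
  beta <- matrix(0, S, 10, dimnames = list(sp, paste0("beta", 1:10)))
  phi <- lapply(pf_n_phi(), function(np)
    matrix(0, S, np, dimnames = list(sp, paste0("phi", seq_len(np)))))
  hyper <- data.frame(family = pf_families(), eta1 = 0, eta2 = 0,
                      sigma = 0.3, stringsAsFactors = FALSE)
  structure(list(
    beta = beta, phi = phi,
    upsilon = stats::setNames(rep(0.5, 4), pf_gears()),
    lm_scalar = 0.8,
    eps_pool = stats::setNames(rep(0, nrow(dataset$pools)),
                               dataset$pools$pool_id),
    eps_time = stats::setNames(rep(0, length(years)), years),
    sigma_pool = 0.3, sigma_time = 0.3,
    hyper = hyper), class = "pf_params")
}

#' Flatten a parameter set to a named vector
#'
#' The naming scheme is stable and used for posterior draw columns and CSV
#' serialization: `beta3[species]`, `phi2.boat_EF[species]`,
#' `eta1[beta1]`, `eta2[phi1.seine_LM]`, `sigma[beta4]`,
#' `eps_pool[pool]`, `eps_time[year]`, `upsilon[gear]`, `lm_scalar`,
#' `sigma_pool`, `sigma_time`.
#'
#' @param params A `pf_params` object.
#' @return Named numeric vector.
#' @export
flatten_params <- function(params) {
  sp <- rownames(params$beta)
  out <- c()
  for (c in 1:10)
    out <- c(out, stats::setNames(params$beta[, c],
                                  sprintf("beta%d[%s]", c, sp)))
  for (g in pf_gears()) {
    np <- pf_n_phi()[[g]]
    for (c in seq_len(np))
      out <- c(out, stats::setNames(params$phi[[g]][, c],
                                    sprintf("phi%d.%s[%s]", c, g, sp)))
  }
  fam <- params$hyper$family
  out <- c(out,
           stats::setNames(params$hyper$eta1, sprintf("eta1[%s]", fam)),
           stats::setNames(params$hyper$eta2, sprintf("eta2[%s]", fam)),
           stats::setNames(params$hyper$sigma, sprintf("sigma[%s]", fam)),
           stats::setNames(params$eps_pool,
                           sprintf("eps_pool[%s]", names(params$eps_pool))),
           stats::setNames(params$eps_time,
                           sprintf("eps_time[%s]", names(params$eps_time))),
           sigma_pool = params$sigma_pool,
           sigma_time = params$sigma_time,
           stats::setNames(params$upsilon,
                           sprintf("upsilon[%s]", pf_gears())),
           lm_scalar = params$lm_scalar)
  out
}

#' Rebuild a parameter set from a flattened named vector
#'
#' Inverse of [flatten_params()] given the dataset that defines the
#' species, pools and years.
#'
#' @param x Named numeric vector in the [flatten_params()] scheme.
#' @param dataset The `survey_dataset` the parameters belong to.
#' @return A `pf_params` object.
#' @export
unflatten_params <- function(x, dataset) {
  p <- params_template(dataset)
  tmpl <- flatten_params(p)
  miss <- setdiff(names(tmpl), names(x))
  if (length(miss))
    stop("missing parameter(s): ", paste(utils::head(miss, 5),
                                         collapse = ", "))
  v <- x[names(tmpl)]
  sp <- rownames(p$beta); S <- length(sp)
  idx <- 0L
  take <- function(n) {
    out <- v[idx + seq_len(n)]; idx <<- idx + n; out
  }
  for (c in 1:10) p$beta[, c] <- take(S)
  for (g in pf_gears())
    for (c in seq_len(pf_n_phi()[[g]])) p$phi[[g]][, c] <- take(S)
  nf <- nrow(p$hyper)
  p$hyper$eta1 <- unname(take(nf))
  p$hyper$eta2 <- unname(take(nf))
  p$hyper$sigma <- unname(take(nf))
  p$eps_pool[] <- take(length(p$eps_pool))
  p$eps_time[] <- take(length(p$eps_time))
  p$sigma_pool <- unname(take(1))
  p$sigma_time <- unname(take(1))
  p$upsilon[] <- take(4)
  p$lm_scalar <- unname(take(1))
  p
}

#' Write / read a parameter set as a flat CSV table
#'
#' @param params A `pf_params` object.
#' @param path CSV file path.
#' @return `path` invisibly (write); a named vector (read).
#' @export
write_params <- function(params, path) {
  v <- flatten_params(params)
  write.csv(data.frame(parameter = names(v), value = unname(v)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @param dataset Dataset defining the parameter layout.
#' @export
read_params <- function(path, dataset) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  unflatten_params(stats::setNames(df$value, df$parameter), dataset)
}
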