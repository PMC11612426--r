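#' Posterior-mean marginal detection probability per sample
#'
#' For each posterior draw, the probability of detecting the species in
#' a sample marginal over latent abundance is
#' \eqn{1 - \sum_N Pois(N|\lambda)(1-r)^N}, computed by the same
#' truncated sum the likelihood uses; the result is averaged over draws.
#'
#' @param posterior A `pf_posterior`, or a single `pf_params` set.
#' @param dataset The scaled `survey_dataset` (defaults to the fit's).
#' @param max_draws Cap on posterior draws used (evenly thinned).
#' @return Species x sample matrix of posterior-mean detection
#'   probabilities.
#' @export
predictive_detection_prob <- function(posterior,
                                      dataset = posterior$dataset,
                                      max_draws = 100) {
  draws <- as_param_draws(posterior, dataset, max_draws)
  sa <- dataset$samples
  visit_of <- match(sa$visit_id, dataset$visits$visit_id)
  acc <- NULL
  for (pr in draws) {
    st <- latent_state(pr, dataset)
    pm <- matrix(0, nrow(dataset$species), nrow(sa),
                 dimnames = dimnames(st$r))
    for (n in seq_len(nrow(sa))) {
      j <- visit_of[n]
      for (i in seq_len(nrow(dataset$species)))
        pm[i, n] <- marginal_detection_prob(st$lambda[i, j],
                                            st$r[i, n])
    }
    acc <- if (is.null(acc)) pm else acc + pm
  }
  acc / length(draws)
}

#' Marginal detection probability of a single sample
#'
#' \eqn{1 - \sum_{N} Pois(N|\lambda)(1-r)^N} via the adaptive truncated
#' sum (the N-marginal of the detection model for one sample).
#'
#' @param lambda Expected abundance (scalar).
#' @param r Capture probability (scalar).
#' @param N_max Optional fixed truncation.
#' @return Detection probability.
#' @export
marginal_detection_prob <- function(lambda, r, N_max = NULL) {
  if (lambda == 0 || r == 0) return(0)
  if (is.null(N_max)) N_max <- n_max_adaptive(lambda)
  N <- 0:N_max
  1 - sum(dpois(N, lambda) *
            exp(N * log1p(-min(r, 1 - 1e-12))))
}

#' Model fidelity: thresholded detection accuracy
#'
#' Classifies each masked (species, visit, sample) cell as predicted
#' detection when its posterior-mean detection probability reaches the
#' threshold, and scores agreement with the observed detections. This is
#' this package's fidelity definition (threshold 0.5 by default,
#' configurable); it is computed within-sample on the fitted data.
#'
#' @param pred Species x sample matrix from
#'   [predictive_detection_prob()].
#' @param dataset The `survey_dataset` holding observed detections.
#' @param threshold Classification threshold (default 0.5).
#' @return Object of class `pf_fidelity_report`: list with `per_species`
#'   (percent accuracy), `overall` (percent), and `gear_calibration`
#'   (per gear: mean predicted probability vs observed detection rate).
#' @export
fidelity <- function(pred, dataset, threshold = 0.5) {
  sa <- dataset$samples
  if (nrow(sa) == 0) stop("empty sample mask")
  visit_of <- match(sa$visit_id, dataset$visits$visit_id)
  S <- nrow(dataset$species)
  yobs <- matrix(0L, S, nrow(sa))
  for (i in seq_len(S))
    yobs[i, ] <- dataset$y[cbind(i, visit_of, sa$k)]
  stopifnot(all(dim(pred) == dim(yobs)))
  hit <- (pred >= threshold) == (yobs == 1)
  per_species <- 100 * rowMeans(hit)
  names(per_species) <- dataset$species$species_id
  gear_calibration <- do.call(rbind, lapply(pf_gears(), function(g) {
    idx <- sa$gear == g
    if (!any(idx)) return(NULL)
    data.frame(gear = g,
               mean_predicted = mean(pred[, idx]),
               observed_rate = mean(yobs[, idx]),
               n_cells = sum(idx) * S)
  }))
  structure(list(per_species = per_species,
                 overall = 100 * mean(hit),
                 threshold = threshold,
                 gear_calibration = gear_calibration),
            class = "pf_fidelity_report")
}

#' @export
print.pf_fidelity_report <- function(x, ...) {
  cat("fidelity (threshold ", x$threshold, "): overall ",
      round(x$overall, 1), "%, species range ",
      round(min(x$per_species), 1), "-",
      round(max(x$per_species), 1), "%\n", sep = "")
  invisible(x)
}

#' Posterior-predictive check on per-species detection totals
#'
#' Simulates replicate detection arrays from posterior draws and
#' compares each species' total detection count with the observed one;
#' the p-value is the fraction of replicates at or above the observation.
#' Values near 0 or 1 flag totals the model cannot reproduce.
#'
#' @param posterior A `pf_posterior`, or a single `pf_params` set.
#' @param dataset The scaled `survey_dataset` (defaults to the fit's).
#' @param n_rep Number of replicate datasets (>= 10).
#' @param seed Integer seed for the replicate simulations.
#' @return data.frame per species: observed total, replicate mean,
#'   p-value.
#' @export
ppc_totals <- function(posterior, dataset = posterior$dataset,
                       n_rep = 100, seed = 1) {
  if (n_rep < 10) stop("n_rep must be >= 10")
  draws <- as_param_draws(posterior, dataset, n_rep)
  set.seed(seed)
  use <- if (length(draws) >= n_rep) sample(seq_along(draws), n_rep)
    else sample(seq_along(draws), n_rep, replace = TRUE)
  obs <- rowSums(dataset$y, na.rm = TRUE)
  reps <- matrix(0, length(obs), n_rep)
  for (b in seq_len(n_rep)) {
    st <- latent_state(draws[[use[b]]], dataset)
    sim <- simulate_detections_from_state(st, dataset)
    reps[, b] <- rowSums(sim$y, na.rm = TRUE)
  }
  data.frame(species_id = dataset$species$species_id,
             observed = obs,
             rep_mean = rowMeans(reps),
             p_value = rowMeans(reps >= obs))
}
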