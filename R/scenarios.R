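#' Apply a minimum-depth pumping rule to pool depths
#'
#' A minimum-depth rule permits pumping from a pool only while its depth
#' exceeds the target: full legal extraction draws every deeper pool
#' down to the rule depth and leaves shallower pools untouched,
#' so \eqn{D' = \min(D, rule)}.
#'
#' @param depths_m Raw pool depths (m, > 0).
#' @param rule_m Minimum-depth rule (m, >= 0).
#' @return Modified depths (m).
#' @export
apply_min_depth_rule <- function(depths_m, rule_m) {
  if (rule_m < 0) stop("rule must be >= 0")
  if (any(depths_m < 0)) stop("depths must be >= 0")
  pmin(depths_m, rule_m)
}

#' Apply a percent-reduction (floodplain harvesting) rule
#'
#' Floodplain harvesting removes a share of the water reaching the
#' pools; the rule caps the average percent reduction in pool depth, and
#' full legal extraction is \eqn{D' = D(1-f)}.
#'
#' @param depths_m Raw pool depths (m).
#' @param fraction Depth-reduction fraction in \[0, 1\]; values above
#'   0.9 are outside the evaluated policy range and warn.
#' @return Modified depths (m).
#' @export
apply_percent_reduction <- function(depths_m, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0,1]")
  if (fraction > 0.9)
    warning("fraction beyond the evaluated 0-90% policy range")
  depths_m * (1 - fraction)
}

# species x pool matrix of expected abundance at given raw depths,
# using the frozen training depth divisor, the pool's random effect and
# a generic year (eps_time = 0)
lambda_at_depths <- function(params, dataset, pool_ids, depths_m) {
  po <- dataset$pools[match(pool_ids, dataset$pools$pool_id), ]
  if (anyNA(po$pool_id)) stop("unknown pool_id")
  if (is.null(dataset$scaling)) stop("dataset must be scaled")
  D <- depths_m / dataset$scaling$depth_divisor
  if (any(D < 0)) stop("modified depth must be >= 0")
  eps <- params$eps_pool[po$pool_id]
  if (anyNA(eps)) stop("pool absent from the fitted random-effect set")
  b <- params$beta
  M <- po$mesohabitat; Tb <- po$turbidity_s
  Sx <- po$complexity_s; R <- po$river_km_s
  np <- length(pool_ids)
  lin <- b[, 1, drop = FALSE] %*% t(rep(1, np)) + outer(b[, 3], M) +
    outer(b[, 5], Tb) + outer(b[, 6], Tb * M) +
    outer(b[, 7], Sx) + outer(b[, 8], Sx * M) +
    outer(b[, 9], R) + outer(b[, 10], R * M)
  decay <- exp(outer(b[, 2], rep(1, np)) + outer(b[, 4], M))
  logD <- ifelse(D > 0, log(D), -Inf)
  ll <- sweep(lin - sweep(decay, 2, D, `*`), 2, logD + eps, `+`)
  dimnames(ll) <- list(rownames(b), pool_ids)
  exp(ll)
}

#' Expected number of occupied pools per species
#'
#' Occupancy of a pool is the probability it holds at least one
#' individual under Poisson abundance, \eqn{1 - e^{-\lambda}}; the
#' expected occupied-pool count is the sum over the target pools. Depths
#' may be scenario-modified; they are re-scaled with the frozen training
#' divisor (a zero depth gives \eqn{\lambda = 0}).
#'
#' @param params A `pf_params` parameter set (e.g. one posterior draw).
#' @param dataset The scaled `survey_dataset` the parameters belong to.
#' @param pool_ids Target pools (default: all).
#' @param depths_m Raw depths to evaluate at (default: observed).
#' @return Named numeric vector over species.
#' @export
expected_occupied_pools <- function(params, dataset,
                                    pool_ids = dataset$pools$pool_id,
                                    depths_m = NULL) {
  if (is.null(depths_m))
    depths_m <- dataset$pools$max_depth[match(pool_ids,
                                              dataset$pools$pool_id)]
  lam <- lambda_at_depths(params, dataset, pool_ids, depths_m)
  rowSums(-expm1(-lam))
}

#' Percent loss of distribution between baseline and scenario
#'
#' \eqn{100 (baseline - scenario)/baseline}; negative values are gains
#' (shallow-optimum species can benefit from drawdown) and are never
#' clipped. A zero baseline is undefined and returns `NA`.
#'
#' @param baseline,scenario Expected occupied-pool counts.
#' @return Percent loss (may be negative), `NA` where baseline is 0.
#' @export
distribution_loss <- function(baseline, scenario) {
  out <- 100 * (baseline - scenario) / baseline
  out[baseline == 0] <- NA_real_
  out
}

#' Define a water-take management scenario
#'
#' @param kind `"min_depth"` (minimum-depth pumping rule, applied to
#'   main-channel pools) or `"percent_reduction"` (floodplain
#'   harvesting, applied to floodplain pools).
#' @param grid Rule grid; defaults to 0.5--2.0 m in 0.05-m steps
#'   (31 rules) for `min_depth` and 0--90% in 2% steps (46 rules) for
#'   `percent_reduction`.
#' @param objectives Distribution-loss objectives (percent); default
#'   < 5 / 10 / 15%.
#' @param target_mesohabitat 0 or 1; defaults to main channel for
#'   `min_depth` and floodplain for `percent_reduction`.
#' @param summary How per-species loss is summarized across posterior
#'   draws before objective counting (`"mean"`, the default, or a
#'   quantile like `"q95"`).
#' @return Object of class `pf_scenario_spec`.
#' @export
scenario_spec <- function(kind = c("min_depth", "percent_reduction"),
                          grid = NULL, objectives = c(5, 10, 15),
                          target_mesohabitat = NULL,
                          summary = "mean") {
  kind <- match.arg(kind)
  if (is.null(grid))
    grid <- if (kind == "min_depth") seq(0.5, 2.0, by = 0.05) else
      seq(0, 0.9, by = 0.02)
  if (is.unsorted(grid)) stop("rule grid must be sorted increasing")
  if (kind == "percent_reduction" && any(grid < 0 | grid > 1))
    stop("percent_reduction grid must be fractions in [0,1]")
  if (is.null(target_mesohabitat))
    target_mesohabitat <- if (kind == "min_depth") 0L else 1L
  structure(list(kind = kind, grid = grid, objectives = objectives,
                 target_mesohabitat = as.integer(target_mesohabitat),
                 summary = summary),
            class = "pf_scenario_spec")
}

# coerce a posterior / single parameter set to a list of pf_params draws
as_param_draws <- function(posterior, dataset, max_draws) {
  if (inherits(posterior, "pf_params")) return(list(posterior))
  if (inherits(posterior, "pf_posterior")) {
    m <- posterior_matrix(posterior)
    idx <- if (nrow(m) > max_draws)
      round(seq(1, nrow(m), length.out = max_draws)) else seq_len(nrow(m))
    return(lapply(idx, function(d) unflatten_params(m[d, ], dataset)))
  }
  stop("posterior must be a pf_posterior or pf_params")
}

#' Evaluate a water-take scenario over its rule grid
#'
#' For every posterior draw and every rule, pool depths in the target
#' mesohabitat are modified (drawn down to the minimum-depth rule, or
#' reduced by the percent-reduction fraction), species occupancy is
#' re-predicted with the frozen covariate scaling, and the percent loss
#' in expected occupied pools is computed within-draw against the
#' same-draw baseline at observed depths. Losses are then summarized
#' across draws and counted against the loss objectives.
#'
#' @param posterior A `pf_posterior` fit, or a single `pf_params` set (a
#'   posterior collapsed to known parameters).
#' @param spec A [scenario_spec()].
#' @param dataset The scaled `survey_dataset` (defaults to the fit's).
#' @param max_draws Cap on posterior draws used (evenly thinned).
#' @return Object of class `pf_scenario_result`: list with `kind`,
#'   `grid`, `objectives`, `species` (per species x rule: baseline,
#'   scenario, mean loss and 5--95% interval), `objective_counts` (per
#'   rule x objective: species meeting it), `species_rules` (per species
#'   x objective: most liberal rule meeting it), and `excluded` (species
#'   with zero baseline, excluded from counting with a warning).
#' @export
objective_curve <- function(posterior, spec,
                            dataset = posterior$dataset,
                            max_draws = 200) {
  stopifnot(inherits(spec, "pf_scenario_spec"))
  target <- dataset$pools$pool_id[
    dataset$pools$mesohabitat == spec$target_mesohabitat]
  if (!length(target)) stop("empty target pool set")
  depths0 <- dataset$pools$max_depth[match(target,
                                           dataset$pools$pool_id)]
  draws <- as_param_draws(posterior, dataset, max_draws)
  S <- nrow(dataset$species)
  nR <- length(spec$grid); nD <- length(draws)

  base <- matrix(0, S, nD)
  loss <- array(NA_real_, c(S, nR, nD))
  scen <- array(NA_real_, c(S, nR, nD))
  for (d in seq_len(nD)) {
    base[, d] <- expected_occupied_pools(draws[[d]], dataset, target,
                                         depths0)
    for (g in seq_len(nR)) {
      mod <- if (spec$kind == "min_depth")
        apply_min_depth_rule(depths0, spec$grid[g]) else
          apply_percent_reduction(depths0, spec$grid[g])
      scen[, g, d] <- expected_occupied_pools(draws[[d]], dataset,
                                              target, mod)
      loss[, g, d] <- distribution_loss(base[, d], scen[, g, d])
    }
  }

  summ <- function(x) {
    if (spec$summary == "mean") mean(x) else
      quantile(x, as.numeric(sub("q", "", spec$summary)) / 100,
               names = FALSE)
  }
  sp_id <- dataset$species$species_id
  species <- do.call(rbind, lapply(seq_len(S), function(i)
    data.frame(species_id = sp_id[i], rule = spec$grid,
               baseline = mean(base[i, ]),
               scenario = apply(scen[i, , , drop = FALSE], 2, mean),
               loss = apply(loss[i, , , drop = FALSE], 2, summ),
               loss_q05 = apply(loss[i, , , drop = FALSE], 2,
                                quantile, 0.05, names = FALSE),
               loss_q95 = apply(loss[i, , , drop = FALSE], 2,
                                quantile, 0.95, names = FALSE),
               row.names = NULL)))
  excluded <- sp_id[apply(base == 0, 1, all)]
  if (length(excluded))
    warning("species with zero baseline excluded from objective ",
            "counting: ", paste(excluded, collapse = ", "),
            call. = FALSE)

  lmat <- matrix(species$loss, nR, S)  # rules x species
  counted <- !(sp_id %in% excluded)
  objective_counts <- do.call(rbind, lapply(spec$objectives, function(o)
    data.frame(rule = spec$grid, objective = o,
               n_species = rowSums(lmat[, counted, drop = FALSE] < o,
                                   na.rm = TRUE))))
  # most liberal rule still meeting the objective: the smallest
  # minimum-depth rule, or the largest reduction fraction
  species_rules <- do.call(rbind, lapply(seq_len(S), function(i) {
    do.call(rbind, lapply(spec$objectives, function(o) {
      ok <- which(lmat[, i] < o)
      rule <- if (!length(ok) || !counted[i]) NA_real_ else
        if (spec$kind == "min_depth") spec$grid[min(ok)] else
          spec$grid[max(ok)]
      data.frame(species_id = sp_id[i], objective = o,
                 most_liberal_rule = rule)
    }))
  }))
  structure(list(kind = spec$kind, grid = spec$grid,
                 objectives = spec$objectives, species = species,
                 objective_counts = objective_counts,
                 species_rules = species_rules, excluded = excluded),
            class = "pf_scenario_result")
}

#' @export
print.pf_scenario_result <- function(x, ...) {
  cat("pf_scenario_result (", x$kind, "): ",
      length(unique(x$species$species_id)), " species x ",
      length(x$grid), " rules\n", sep = "")
  for (o in x$objectives) {
    oc <- x$objective_counts[x$objective_counts$objective == o, ]
    full <- oc$rule[oc$n_species == max(oc$n_species)]
    lib <- if (x$kind == "min_depth") min(full) else max(full)
    cat("  <", o, "% loss: all-species rule ",
        if (x$kind == "min_depth") paste0(lib, " m") else
          paste0(100 * lib, "% reduction"), "\n", sep = "")
  }
  invisible(x)
}
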