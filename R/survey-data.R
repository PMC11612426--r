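#' Gear types recognised by the survey data model
#'
#' Four gears are modelled: backpack electrofishing, boat electrofishing,
#' large-mesh seine (10-m standard, with a 5-m variant) and small-mesh
#' seine. Effort units are seconds of power for the electrofishing gears
#' and metres hauled for the seines.
#'
#' @return Character vector of the four gear codes.
#' @export
pf_gears <- function() {
  c("backpack_EF", "boat_EF", "seine_LM", "seine_SM")
}

#' @rdname pf_gears
#' @export
pf_ef_gears <- function() c("backpack_EF", "boat_EF")

# number of catchability coefficients per gear: conductivity (phi6) is
# modelled only for electrofishing gears
pf_n_phi <- function() c(backpack_EF = 6L, boat_EF = 6L,
                         seine_LM = 5L, seine_SM = 5L)

#' Construct a multi-gear pool survey dataset
#'
#' Bundles the five survey tables (species, pools, visits, samples,
#' detections) into a validated `survey_dataset` object, the container all
#' model-fitting, simulation and scenario functions operate on.
#'
#' @param species data.frame with columns `species_id` (character) and
#'   `mean_length` (positive, mm).
#' @param pools data.frame with columns `pool_id`, `mesohabitat`
#'   (0 = main channel, 1 = floodplain), `max_depth` (m, > 0), `turbidity`
#'   (NTU, >= 0), `complexity` (percent cover, 0--100), `river_km`
#'   (km upstream of the estuary, >= 0), `conductivity` (> 0; may be `NA`
#'   if no electrofishing sample uses the pool).
#' @param visits data.frame with columns `visit_id`, `pool_id`, `year`.
#'   One row per pool x year site-visit.
#' @param samples data.frame with columns `sample_id`, `visit_id`, `gear`
#'   (one of [pf_gears()]), `effort_raw` (> 0), `sample_depth` (m, > 0),
#'   `sample_complexity` (percent, may be `NA`: imputed from the pool
#'   value), `seine_variant` (`"none"`, `"seine5m"` or `"seine10m"`;
#'   non-`"none"` exactly for `seine_LM` samples).
#' @param y Optional detection array (species x visit x sample slot),
#'   binary inside the validity mask, `NA` outside. Built with
#'   [binarize_catch()] or by [load_survey()].
#' @param scaling Optional scaling metadata from [scale_covariates()].
#' @param truth Optional generating-truth bundle attached by
#'   [simulate_survey()].
#'
#' @return An object of class `survey_dataset`: a list with elements
#'   `species`, `pools`, `visits`, `samples`, `y`, `scaling`, `truth`.
#'   Samples carry a within-visit slot index `k`.
#' @export
survey_dataset <- function(species, pools, visits, samples, y = NULL,
                           scaling = NULL, truth = NULL) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  pools   <- as.data.frame(pools, stringsAsFactors = FALSE)
  visits  <- as.data.frame(visits, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("missing column", if (length(miss) > 1) "s", " in ", what,
           " table: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  need(species, c("species_id", "mean_length"), "species")
  need(pools, c("pool_id", "mesohabitat", "max_depth", "turbidity",
                "complexity", "river_km", "conductivity"), "pools")
  need(visits, c("visit_id", "pool_id", "year"), "visits")
  need(samples, c("sample_id", "visit_id", "gear", "effort_raw",
                  "sample_depth", "sample_complexity", "seine_variant"),
       "samples")

  if (anyDuplicated(species$species_id)) stop("duplicate species_id")
  if (anyDuplicated(pools$pool_id)) stop("duplicate pool_id")
  if (anyDuplicated(visits$visit_id)) stop("duplicate visit_id")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (anyDuplicated(visits[c("pool_id", "year")]))
    stop("duplicate (pool_id, year) site-visit")

  if (any(species$mean_length <= 0)) stop("mean_length must be > 0")
  if (!all(pools$mesohabitat %in% c(0, 1)))
    stop("mesohabitat must be 0 (main channel) or 1 (floodplain)")
  if (any(pools$max_depth <= 0)) stop("pool max_depth must be > 0")
  if (any(pools$turbidity < 0)) stop("turbidity must be >= 0")
  if (any(pools$complexity < 0 | pools$complexity > 100))
    stop("complexity must be within 0--100 percent")
  if (any(pools$river_km < 0)) stop("river_km must be >= 0")

  if (!all(visits$pool_id %in% pools$pool_id))
    stop("orphan reference: visit references unknown pool_id")
  if (!all(samples$visit_id %in% visits$visit_id))
    stop("orphan reference: sample references unknown visit_id")
  if (!all(samples$gear %in% pf_gears()))
    stop("unknown gear code in samples table")
  if (any(samples$effort_raw <= 0)) stop("effort_raw must be > 0")
  if (any(samples$sample_depth <= 0)) stop("sample_depth must be > 0")
  bad_var <- (samples$gear == "seine_LM") !=
    (samples$seine_variant %in% c("seine5m", "seine10m"))
  if (any(bad_var))
    stop("seine_variant must be seine5m/seine10m exactly for seine_LM samples")
  if (nrow(samples) > 0 && !all(visits$visit_id %in% samples$visit_id))
    stop("every visit needs at least one sample")

  # EF samples need a usable pool conductivity
  ef_pools <- visits$pool_id[match(
    samples$visit_id[samples$gear %in% pf_ef_gears()], visits$visit_id)]
  if (any(is.na(pools$conductivity[match(ef_pools, pools$pool_id)])))
    stop("missing conductivity for a pool with electrofishing samples")

  # within-visit sample slot index (order of appearance)
  samples$k <- stats::ave(seq_len(nrow(samples)), samples$visit_id,
                          FUN = seq_along)
  # impute missing sample-scale complexity from the pool value, flagged
  if (!"complexity_imputed" %in% names(samples))
    samples$complexity_imputed <- FALSE
  na_sc <- is.na(samples$sample_complexity)
  if (any(na_sc)) {
    pool_of <- visits$pool_id[match(samples$visit_id, visits$visit_id)]
    samples$sample_complexity[na_sc] <-
      pools$complexity[match(pool_of, pools$pool_id)][na_sc]
    samples$complexity_imputed[na_sc] <- TRUE
  }

  if (!is.null(y)) {
    y <- validate_detection_array(y, species, visits, samples)
  }

  structure(list(species = species, pools = pools, visits = visits,
                 samples = samples, y = y, scaling = scaling,
                 truth = truth),
            class = "survey_dataset")
}

# check a detection array against the tables; returns the array with
# canonical dimnames
validate_detection_array <- function(y, species, visits, samples) {
  S <- nrow(species); J <- nrow(visits)
  Kmax <- if (nrow(samples)) max(samples$k) else 0L
  if (!is.array(y) || length(dim(y)) != 3 ||
      !all(dim(y) == c(S, J, Kmax)))
    stop("detection array must have dim (n_species, n_visits, max samples)")
  mask <- detection_mask(visits, samples)
  for (j in seq_len(J)) {
    kj <- mask[j, ]
    yv <- y[, j, kj, drop = FALSE]
    if (anyNA(yv) || !all(yv %in% c(0L, 1L)))
      stop("non-binary detection value inside the validity mask")
    if (Kmax > sum(kj) && !all(is.na(y[, j, !kj])))
      stop("detection values present outside the validity mask")
  }
  dimnames(y) <- list(species$species_id, visits$visit_id, NULL)
  storage.mode(y) <- "integer"
  y
}

# J x Kmax logical mask of realized sample slots
detection_mask <- function(visits, samples) {
  J <- nrow(visits)
  Kmax <- if (nrow(samples)) max(samples$k) else 0L
  mask <- matrix(FALSE, J, Kmax,
                 dimnames = list(visits$visit_id, NULL))
  if (Kmax)
    mask[cbind(match(samples$visit_id, visits$visit_id), samples$k)] <- TRUE
  mask
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("survey_dataset:", nrow(x$species), "species,", nrow(x$pools),
      "pools (", sum(x$pools$mesohabitat == 0), "main channel /",
      sum(x$pools$mesohabitat == 1), "floodplain ),",
      nrow(x$visits), "site-visits,", nrow(x$samples), "samples\n")
  cat("  gears:", paste(names(table(x$samples$gear)),
                        table(x$samples$gear), collapse = ", "), "\n")
  cat("  detections:", if (is.null(x$y)) "none" else
    sum(x$y, na.rm = TRUE), "| scaled:",
    !is.null(x$scaling), "| truth attached:", !is.null(x$truth), "\n")
  invisible(x)
}

#' Binarize a catch-count tensor into detection/non-detection
#'
#' The model likelihood uses detection/non-detection data only: a species
#' is detected in a sample when at least one individual was caught.
#'
#' @param counts Non-negative integer vector, matrix or array of catch
#'   counts; `NA` entries (masked cells) are preserved.
#' @return Integer object of the same shape with 1 where `counts >= 1`,
#'   0 where `counts == 0`, `NA` where masked.
#' @export
binarize_catch <- function(counts) {
  if (any(counts < 0, na.rm = TRUE)) stop("negative count")
  y <- counts
  y[!is.na(counts)] <- as.integer(counts[!is.na(counts)] >= 1)
  storage.mode(y) <- "integer"
  y
}

#' Remove rarely detected species from a survey dataset
#'
#' Species caught at too few sampling events carry almost no information
#' about depth response and destabilize the species hierarchy, so they are
#' removed before fitting. A sampling event is a site-visit at which the
#' species was detected in at least one sample (gears vary within a visit,
#' so the visit is the natural unit).
#'
#' @param dataset A `survey_dataset` with a detection array.
#' @param min_events Minimum number of detection site-visits required to
#'   retain a species. The default 3 removes species detected on two or
#'   fewer site-visits.
#' @return The filtered `survey_dataset`; removed species ids are attached
#'   as attribute `"removed_species"`. Idempotent. If covariates were
#'   already scaled, the species length standardization is recomputed on
#'   the retained species.
#' @export
filter_rare_species <- function(dataset, min_events = 3L) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (min_events < 1) stop("min_events must be >= 1")
  if (is.null(dataset$y)) stop("detection array not built yet")
  if (nrow(dataset$species) == 0L) {
    attr(dataset, "removed_species") <- character(0)
    return(dataset)
  }
  events <- species_detection_events(dataset)
  keep <- events >= min_events
  removed <- dataset$species$species_id[!keep]
  dataset$species <- dataset$species[keep, , drop = FALSE]
  rownames(dataset$species) <- NULL
  dataset$y <- dataset$y[keep, , , drop = FALSE]
  if (!is.null(dataset$scaling)) {
    # re-standardize length over the retained (modelled) species
    ln <- standardize(dataset$species$mean_length)
    dataset$species$length_std <- ln$x
    dataset$scaling$length_center <- ln$center
    dataset$scaling$length_sd <- ln$sd
  }
  attr(dataset, "removed_species") <- removed
  dataset
}

#' Number of site-visits with at least one detection, per species
#'
#' @param dataset A `survey_dataset` with a detection array.
#' @return Named integer vector over species.
#' @export
species_detection_events <- function(dataset) {
  det <- apply(dataset$y, c(1, 2), function(v) any(v == 1, na.rm = TRUE))
  ev <- rowSums(det)
  stats::setNames(as.integer(ev), dataset$species$species_id)
}

# population standardization (divide by sqrt(mean squared deviation)) so
# the constants are exactly reproducible from the stored tables
standardize <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s <= 0) stop("zero-variance covariate (cannot standardize)")
  list(x = (x - m) / s, center = m, sd = s)
}

#' Scale survey covariates for model fitting
#'
#' Depth covariates and effort are divided by their maxima so that the
#' scaled values lie in (0, 1] (the Ricker depth term requires a
#' unit-scaled depth); turbidity, complexity, river kilometre,
#' conductivity and species mean length are centered to mean zero and
#' scaled to unit (population) standard deviation. All constants are
#' frozen in the `scaling` element so that predictions on modified or new
#' pools reuse the training divisors and the transforms can be inverted.
#'
#' @param dataset A `survey_dataset` with raw covariates.
#' @return The dataset with scaled columns added (`pools$depth_s`,
#'   `pools$turbidity_s`, `pools$complexity_s`, `pools$river_km_s`,
#'   `pools$conductivity_s`, `samples$sample_depth_s`,
#'   `samples$sample_complexity_s`, `samples$effort_s`,
#'   `species$length_std`) and `scaling` populated.
#' @export
scale_covariates <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  p <- dataset$pools; s <- dataset$samples; sp <- dataset$species

  depth_divisor <- max(p$max_depth)
  sample_depth_divisor <- max(s$sample_depth)
  effort_divisor <- vapply(pf_gears(), function(g) {
    e <- s$effort_raw[s$gear == g]
    if (length(e)) max(e) else NA_real_
  }, numeric(1))

  p$depth_s <- p$max_depth / depth_divisor
  tu <- standardize(p$turbidity);   p$turbidity_s <- tu$x
  cx <- standardize(p$complexity);  p$complexity_s <- cx$x
  rk <- standardize(p$river_km);    p$river_km_s <- rk$x
  # conductivity may be NA for pools never electrofished; standardize on
  # the observed values
  co_obs <- !is.na(p$conductivity)
  co <- standardize(p$conductivity[co_obs])
  p$conductivity_s <- NA_real_
  p$conductivity_s[co_obs] <- co$x

  s$sample_depth_s <- s$sample_depth / sample_depth_divisor
  s$sample_complexity_s <- (s$sample_complexity - cx$center) / cx$sd
  s$effort_s <- s$effort_raw / effort_divisor[s$gear]

  ln <- standardize(sp$mean_length)
  sp$length_std <- ln$x

  dataset$pools <- p; dataset$samples <- s; dataset$species <- sp
  dataset$scaling <- list(
    depth_divisor = depth_divisor,
    sample_depth_divisor = sample_depth_divisor,
    effort_divisor = effort_divisor,
    turbidity_center = tu$center, turbidity_sd = tu$sd,
    complexity_center = cx$center, complexity_sd = cx$sd,
    river_km_center = rk$center, river_km_sd = rk$sd,
    conductivity_center = co$center, conductivity_sd = co$sd,
    length_center = ln$center, length_sd = ln$sd)
  dataset
}

#' Invert the covariate scaling
#'
#' Recovers raw covariates from the scaled columns using the frozen
#' constants; used for reporting and round-trip validation.
#'
#' @param dataset A scaled `survey_dataset`.
#' @return List of raw covariate vectors (`max_depth`, `turbidity`,
#'   `complexity`, `river_km`, `conductivity`, `sample_depth`,
#'   `effort_raw`, `mean_length`).
#' @export
unscale_covariates <- function(dataset) {
  sc <- dataset$scaling
  if (is.null(sc)) stop("dataset has no scaling info")
  p <- dataset$pools; s <- dataset$samples
  list(max_depth = p$depth_s * sc$depth_divisor,
       turbidity = p$turbidity_s * sc$turbidity_sd + sc$turbidity_center,
       complexity = p$complexity_s * sc$complexity_sd + sc$complexity_center,
       river_km = p$river_km_s * sc$river_km_sd + sc$river_km_center,
       conductivity = p$conductivity_s * sc$conductivity_sd +
         sc$conductivity_center,
       sample_depth = s$sample_depth_s * sc$sample_depth_divisor,
       effort_raw = unname(s$effort_s * sc$effort_divisor[s$gear]),
       mean_length = dataset$species$length_std * sc$length_sd +
         sc$length_center)
}

#' Read a survey dataset from delimited tables
#'
#' Reads the five survey tables from a directory (`species.csv`,
#' `pools.csv`, `visits.csv`, `samples.csv`, `catch.csv`), builds the
#' detection array by binarizing catch counts, and validates referential
#' integrity. `catch.csv` is long format with columns `species_id`,
#' `sample_id`, `count` (or `detected`); absent combinations are
#' non-detections.
#'
#' @param tables_path Directory containing the tables.
#' @param config Optional options: a named list, or path to a YAML/JSON
#'   file, with elements `files` (named overrides of the five file names)
#'   and/or `min_events` (if present, [filter_rare_species()] is applied).
#' @return A validated `survey_dataset`.
#' @export
load_survey <- function(tables_path, config = NULL) {
  config <- read_config(config)
  files <- c(species = "species.csv", pools = "pools.csv",
             visits = "visits.csv", samples = "samples.csv",
             catch = "catch.csv")
  if (!is.null(config$files)) files[names(config$files)] <-
      unlist(config$files)
  paths <- file.path(tables_path, files)
  names(paths) <- names(files)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing survey table file(s): ",
         paste(files[missing], collapse = ", "))
  tab <- lapply(paths, read.csv, stringsAsFactors = FALSE,
                colClasses = NA)
  for (nm in c("species", "pools", "visits", "samples")) {
    idcol <- c(species = "species_id", pools = "pool_id",
               visits = "visit_id", samples = "sample_id")[nm]
    if (idcol %in% names(tab[[nm]]))
      tab[[nm]][[idcol]] <- as.character(tab[[nm]][[idcol]])
  }
  # measured quantities are doubles regardless of how they print
  numcols <- list(species = "mean_length",
                  pools = c("max_depth", "turbidity", "complexity",
                            "river_km", "conductivity"),
                  samples = c("effort_raw", "sample_depth",
                              "sample_complexity"))
  for (nm in names(numcols))
    for (cc in intersect(numcols[[nm]], names(tab[[nm]])))
      tab[[nm]][[cc]] <- as.numeric(tab[[nm]][[cc]])
  if ("visit_id" %in% names(tab$samples))
    tab$samples$visit_id <- as.character(tab$samples$visit_id)
  if ("pool_id" %in% names(tab$visits))
    tab$visits$pool_id <- as.character(tab$visits$pool_id)

  ds <- survey_dataset(tab$species, tab$pools, tab$visits, tab$samples)

  catch <- tab$catch
  need <- c("species_id", "sample_id")
  if (!all(need %in% names(catch)))
    stop("missing column in catch table: ",
         paste(setdiff(need, names(catch)), collapse = ", "))
  valcol <- if ("count" %in% names(catch)) "count" else
    if ("detected" %in% names(catch)) "detected" else
      stop("missing column in catch table: count (or detected)")
  if (!all(catch$species_id %in% ds$species$species_id))
    stop("orphan reference: catch references unknown species_id")
  if (!all(catch$sample_id %in% ds$samples$sample_id))
    stop("orphan reference: catch references unknown sample_id")

  y <- detection_array_from_catch(ds, catch, valcol)
  ds$y <- validate_detection_array(y, ds$species, ds$visits, ds$samples)
  if (!is.null(config$min_events))
    ds <- filter_rare_species(ds, config$min_events)
  ds
}

# build (S, J, Kmax) detection array from a long catch table
detection_array_from_catch <- function(ds, catch, valcol = "count") {
  S <- nrow(ds$species); J <- nrow(ds$visits)
  Kmax <- max(ds$samples$k)
  counts <- array(NA_real_, c(S, J, Kmax))
  jk <- cbind(match(ds$samples$visit_id, ds$visits$visit_id),
              ds$samples$k)
  for (r in seq_len(nrow(ds$samples))) counts[, jk[r, 1], jk[r, 2]] <- 0
  i <- match(catch$species_id, ds$species$species_id)
  srow <- match(catch$sample_id, ds$samples$sample_id)
  counts[cbind(i, jk[srow, 1], jk[srow, 2])] <- catch[[valcol]]
  binarize_catch(counts)
}

#' Write a survey dataset as normalized delimited tables
#'
#' Writes `species.csv`, `pools.csv`, `visits.csv`, `samples.csv` and
#' `catch.csv` (long detection table) so that [load_survey()] of the
#' output reproduces the input tables bit-identically. Scaled columns are
#' not written; if the dataset carries scaling metadata or a simulation
#' truth bundle those are written alongside as `scaling.csv` /
#' `truth_*.csv` for reference.
#'
#' @param dataset A `survey_dataset`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_survey <- function(dataset, path) {
  stopifnot(inherits(dataset, "survey_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  raw_species <- dataset$species[c("species_id", "mean_length")]
  raw_pools <- dataset$pools[c("pool_id", "mesohabitat", "max_depth",
                               "turbidity", "complexity", "river_km",
                               "conductivity")]
  raw_visits <- dataset$visits[c("visit_id", "pool_id", "year")]
  raw_samples <- dataset$samples[c("sample_id", "visit_id", "gear",
                                   "effort_raw", "sample_depth",
                                   "sample_complexity", "seine_variant")]
  # imputed sample complexity is provenance, not data: write it back
  # as missing so a reload imputes identically
  raw_samples$sample_complexity[dataset$samples$complexity_imputed] <-
    NA_real_
  wr <- function(df, f) write.csv(df, file.path(path, f),
                                  row.names = FALSE, quote = FALSE)
  wr(raw_species, "species.csv")
  wr(raw_pools, "pools.csv")
  wr(raw_visits, "visits.csv")
  wr(raw_samples, "samples.csv")

  if (!is.null(dataset$y)) {
    jk <- cbind(match(dataset$samples$visit_id, dataset$visits$visit_id),
                dataset$samples$k)
    det <- do.call(rbind, lapply(seq_len(nrow(dataset$species)),
      function(i) {
        yi <- dataset$y[cbind(i, jk[, 1], jk[, 2])]
        hit <- which(yi == 1)
        if (!length(hit)) return(NULL)
        data.frame(species_id = dataset$species$species_id[i],
                   sample_id = dataset$samples$sample_id[hit],
                   detected = 1L)
      }))
    if (is.null(det))
      det <- data.frame(species_id = character(0),
                        sample_id = character(0), detected = integer(0))
    wr(det, "catch.csv")
  }
  if (!is.null(dataset$scaling)) {
    sc <- dataset$scaling
    flat <- data.frame(name = c("depth_divisor", "sample_depth_divisor",
                                paste0("effort_divisor.", pf_gears()),
                                "turbidity_center", "turbidity_sd",
                                "complexity_center", "complexity_sd",
                                "river_km_center", "river_km_sd",
                                "conductivity_center", "conductivity_sd",
                                "length_center", "length_sd"),
                       value = c(sc$depth_divisor, sc$sample_depth_divisor,
                                 sc$effort_divisor,
                                 sc$turbidity_center, sc$turbidity_sd,
                                 sc$complexity_center, sc$complexity_sd,
                                 sc$river_km_center, sc$river_km_sd,
                                 sc$conductivity_center, sc$conductivity_sd,
                                 sc$length_center, sc$length_sd))
    wr(flat, "scaling.csv")
  }
  invisible(path)
}

# accept NULL, a named list, or a path to a YAML/JSON config file
read_config <- function(config) {
  if (is.null(config) || is.list(config)) return(config)
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("jsonlite needed to read JSON config")
      return(jsonlite::fromJSON(config, simplifyVector = TRUE))
    }
    if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml needed to read YAML config")
      return(yaml::read_yaml(config))
    }
    stop("config file must be .json or .yaml")
  }
  stop("config must be NULL, a list, or a path to a YAML/JSON file")
}
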