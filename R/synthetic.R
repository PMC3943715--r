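#' Default per-species simulation parameters
#'
#' Two invasive rodents with the statistical structure a peninsula-wide
#' camera grid would see: a near-ubiquitous black rat (high occupancy,
#' nightly detection declining from an initial bait-novelty peak, high
#' activity) and a patchier house mouse (lower occupancy and detection,
#' low mean activity with strong overdispersion, activity tied to low
#' vegetation and saltbush cover). The detection vectors span 0.30-0.79
#' (rat) and 0.29-0.59 (mouse) and imply 95% confidence in site-level
#' absence after 3 and 5 undetected nights respectively.
#'
#' @return Named list of per-species parameter lists with elements
#'   `psi` (occupancy probability), `p` (nightly detection probability,
#'   scalar or one value per night), `activity_intercept` (log events per
#'   night at average habitat), `activity_betas` (named log-scale effects
#'   of standardized covariates) and `theta` (negative-binomial
#'   dispersion, larger = closer to Poisson).
#' @export
default_species_params <- function() {
  list(
    "black rat" = list(
      psi = 0.90,
      p = c(0.79, 0.72, 0.68, 0.62, 0.55, 0.45, 0.38, 0.30),
      activity_intercept = log(5.4),
      activity_betas = c(C_gt1m = 0.5),
      theta = 0.8
    ),
    "house mouse" = list(
      psi = 0.58,
      p = c(0.59, 0.54, 0.50, 0.45, 0.40, 0.35, 0.31, 0.29),
      activity_intercept = log(1.4),
      activity_betas = c(C_gt1m = -0.3, Rhag = 0.3, C10_40 = 0.3),
      theta = 0.6
    )
  )
}

#' Default habitat-covariate generation parameters
#'
#' Floristic covers are a symmetric-ish Dirichlet over the four dominant
#' species plus "other", scaled to 100%. Structure-pole touches decay with
#' height from a site-level complexity draw. Seabird burrows occur in
#' colonies covering a fraction of sites; within colonies the burrow field
#' is homogeneous Poisson with a Gamma-distributed site intensity.
#'
#' @return List of distribution settings consumed by [simulate_study()].
#' @export
default_covariate_params <- function() {
  list(
    cover_alpha = c(Poa = 2.0, Tetra = 1.5, Rhag = 1.2, Disphyma = 0.8,
                    Other = 1.5),
    c_gt1m_beta = c(shape1 = 1.3, shape2 = 3.0),
    pole_complexity_beta = c(shape1 = 2, shape2 = 4),
    pole_height_decay = 0.25,
    colony_prob = 0.3,
    shearwater_intensity = c(shape = 2, scale = 0.010),
    penguin_intensity = c(shape = 2, scale = 0.004),
    pcq_truncation_m = 40
  )
}

#' Build a synthetic-study configuration
#'
#' @param n_sites number of camera sites (default 276, one camera per
#'   ~1.5 ha across the study area).
#' @param nights_per_site scalar or per-site integer vector of survey
#'   nights (default 8, the nominal deployment length).
#' @param species_params per-species parameter lists; see
#'   [default_species_params()].
#' @param covariate_params habitat generation settings; see
#'   [default_covariate_params()].
#' @param start_time deployment start (POSIXct or parseable string, UTC);
#'   cameras are set mid-afternoon so the first survey night is partial.
#' @param seed integer RNG seed.
#' @return A `study_config` list, validated.
#' @export
study_config <- function(n_sites = 276,
                         nights_per_site = 8,
                         species_params = default_species_params(),
                         covariate_params = default_covariate_params(),
                         start_time = "2012-04-15 14:00:00",
                         seed = 1L) {
  if (!is.numeric(n_sites) || length(n_sites) != 1 || n_sites < 1 ||
      n_sites != round(n_sites)) {
    stop("n_sites must be a positive integer")
  }
  n_sites <- as.integer(n_sites)
  nights_per_site <- as.integer(nights_per_site)
  if (any(nights_per_site < 1)) stop("nights_per_site must be >= 1")
  if (!length(nights_per_site) %in% c(1L, n_sites)) {
    stop("nights_per_site must be scalar or length n_sites")
  }
  for (sp in names(species_params)) {
    pars <- species_params[[sp]]
    if (pars$psi < 0 || pars$psi > 1) {
      stop("psi for '", sp, "' outside [0,1]")
    }
    if (any(pars$p < 0 | pars$p > 1)) {
      stop("p for '", sp, "' outside [0,1]")
    }
    if (pars$theta <= 0) stop("theta for '", sp, "' must be > 0")
  }
  cfg <- list(
    n_sites = n_sites,
    nights_per_site = nights_per_site,
    species_params = species_params,
    covariate_params = covariate_params,
    start_time = as.POSIXct(start_time, tz = "UTC"),
    seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  cfg
}

# noon (12:00 UTC) at or before a timestamp: anchor for survey nights
noon_before <- function(t) {
  day <- as.POSIXct(trunc(t, units = "days"), tz = "UTC")
  noon <- day + 12 * 3600
  noon[noon > t] <- noon[noon > t] - 86400
  noon
}

# zero-truncated negative binomial draws via inverse CDF
rztnbinom <- function(n, mu, size) {
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  u <- runif(n, min = p0, max = 1)
  stats::qnbinom(u, size = size, mu = mu)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a full camera-trap study
#'
#' Generates trigger-level camera records, a deployment log and habitat
#' survey tables with the structure the downstream analysis assumes, plus
#' a truth record for parameter-recovery tests.
#'
#' The nightly activity layer is a hurdle scheme tied to the occupancy
#' layer: a site is occupied by a species with probability `psi`; on each
#' survey night an occupied site is visited with probability `p_t` (so the
#' nightly detection probability is exactly `p_t`); given a visit, the
#' number of 15-min presence events is a zero-truncated negative binomial
#' with mean `lambda_s` and dispersion `theta`, where
#' `log(lambda_s) = activity_intercept + X_s %*% activity_betas` over
#' standardized habitat covariates. Each event occupies a distinct
#' clock-aligned 15-min bin of the night and is expanded into 1-3 camera
#' triggers with timestamps inside its bin. Unoccupied sites emit nothing.
#'
#' @param config a [study_config()].
#' @return List of class `rodent_study` with elements `triggers`
#'   (site_id, timestamp, species), `deployments` (site_id, start, end),
#'   `habitat` (list of `pcq`, `poles`, `covers` data frames),
#'   `covariates` (assembled site covariates used for generation) and
#'   `truth` (latent occupancy `z`, expected rates `lambda`, and all
#'   generating parameters).
#' @seealso [write_study()] to serialize the bundle to CSV/JSON.
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  n <- config$n_sites
  nights <- rep(config$nights_per_site, length.out = n)
  site_ids <- sprintf("S%03d", seq_len(n))
  cp <- config$covariate_params

  # --- deployments: afternoon set-up, retrieved at noon after last night
  start <- rep(config$start_time, n)
  anchor <- noon_before(start)
  end <- anchor + nights * 86400
  deployments <- data.frame(
    site_id = site_ids,
    start = format(start, "%Y-%m-%dT%H:%M:%SZ"),
    end = format(end, "%Y-%m-%dT%H:%M:%SZ"),
    stringsAsFactors = FALSE
  )

  # --- habitat surveys
  covers_mat <- t(vapply(seq_len(n),
                         function(i) rdirichlet1(cp$cover_alpha) * 100,
                         numeric(length(cp$cover_alpha))))
  colnames(covers_mat) <- names(cp$cover_alpha)
  c_gt1m <- round(100 * rbeta(n, cp$c_gt1m_beta[["shape1"]],
                              cp$c_gt1m_beta[["shape2"]]))
  covers <- data.frame(site_id = site_ids, round(covers_mat, 1),
                       C_gt1m = c_gt1m, stringsAsFactors = FALSE)

  complexity <- rbeta(n, cp$pole_complexity_beta[["shape1"]],
                      cp$pole_complexity_beta[["shape2"]])
  decay <- exp(-cp$pole_height_decay * (0:9))
  poles <- do.call(rbind, lapply(seq_len(n), function(i) {
    q <- pmin(1, complexity[i] * decay)
    data.frame(
      site_id = site_ids[i],
      pole = rep(1:8, each = 10),
      band = rep(1:10, times = 8),
      touches = rbinom(80, 10, rep(q, times = 8)),
      stringsAsFactors = FALSE
    )
  }))

  in_colony <- runif(n) < cp$colony_prob
  at_int <- ifelse(in_colony,
                   rgamma(n, shape = cp$shearwater_intensity[["shape"]],
                          scale = cp$shearwater_intensity[["scale"]]), 0)
  em_int <- ifelse(in_colony,
                   rgamma(n, shape = cp$penguin_intensity[["shape"]],
                          scale = cp$penguin_intensity[["scale"]]), 0)
  pcq <- rbind(
    pcq_distances(at_int, site_ids, "shearwater", cp$pcq_truncation_m),
    pcq_distances(em_int, site_ids, "penguin", cp$pcq_truncation_m)
  )

  covariates <- assemble_covariates(pcq, poles, covers,
                                    truncation = cp$pcq_truncation_m)

  # standardized covariates drive the activity layer
  num_cols <- setdiff(names(covariates), "site_id")
  X <- scale(as.matrix(covariates[num_cols]))
  X[is.nan(X)] <- 0  # zero-variance column guard

  # --- per-species occupancy + hurdle-NB activity
  truth <- list(seed = config$seed, n_sites = n, nights = nights,
                species = list())
  trig_list <- list()
  for (sp in names(config$species_params)) {
    pars <- config$species_params[[sp]]
    p_night <- rep(pars$p, length.out = max(nights))
    z <- rbinom(n, 1, pars$psi)
    eta <- rep(pars$activity_intercept, n)
    for (nm in names(pars$activity_betas)) {
      if (!nm %in% colnames(X)) {
        stop("activity_betas names unknown covariate: ", nm)
      }
      eta <- eta + pars$activity_betas[[nm]] * X[, nm]
    }
    lambda <- exp(eta)
    truth$species[[sp]] <- list(psi = pars$psi, p = p_night,
                                theta = pars$theta, z = z, lambda = lambda,
                                activity_intercept = pars$activity_intercept,
                                activity_betas = as.list(pars$activity_betas))
    for (i in seq_len(n)) {
      if (z[i] == 0) next
      for (t in seq_len(nights[i])) {
        if (runif(1) >= p_night[t]) next
        night_start <- anchor[i] + (t - 1) * 86400
        # clock-aligned 15-min bins of this night inside the deployment
        bin_starts <- night_start + 900 * (0:95)
        ok <- bin_starts >= start[i] & (bin_starts + 900) <= end[i] + 900
        avail <- which(ok)
        m <- min(rztnbinom(1, mu = lambda[i], size = pars$theta),
                 length(avail))
        bins <- sample(avail, m)
        for (b in bins) {
          k <- sample(1:3, 1)
          ts <- sort(bin_starts[b] + runif(k, 0, 900))
          ts <- pmax(ts, start[i])  # partial first bin
          trig_list[[length(trig_list) + 1L]] <- data.frame(
            site_id = site_ids[i],
            timestamp = format(ts, "%Y-%m-%dT%H:%M:%OS3Z"),
            species = sp, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  triggers <- if (length(trig_list)) do.call(rbind, trig_list) else
    data.frame(site_id = character(), timestamp = character(),
               species = character(), stringsAsFactors = FALSE)
  triggers <- triggers[order(triggers$site_id, triggers$timestamp), ,
                       drop = FALSE]
  rownames(triggers) <- NULL

  structure(list(triggers = triggers, deployments = deployments,
                 habitat = list(pcq = pcq, poles = poles, covers = covers),
                 covariates = covariates, truth = truth,
                 config = config),
            class = "rodent_study")
}

# quadrant distances for site-specific Poisson burrow intensities
pcq_distances <- function(intensity, site_ids, burrow_type, truncation) {
  n <- length(intensity)
  quad <- c("NE", "NW", "SE", "SW")
  d <- matrix(NA_real_, n, 4)
  pos <- intensity > 0
  if (any(pos)) {
    a <- intensity[pos] * pi / 4
    draws <- sqrt(-log(runif(sum(pos) * 4)) / rep(a, 4))
    draws[draws > truncation] <- NA_real_
    d[pos, ] <- matrix(draws, ncol = 4)
  }
  data.frame(
    site_id = rep(site_ids, times = 4),
    quadrant = rep(quad, each = n),
    burrow_type = burrow_type,
    distance_m = round(as.vector(d), 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate detection histories directly from the occupancy model
#'
#' Bypasses the trigger/event layer: latent occupancy `z_s ~ Bern(psi)`
#' and nightly detections `y_st ~ Bern(z_s * p_t)`.
#'
#' @param psi occupancy probability.
#' @param p nightly detection probability: scalar (with `n_nights`) or a
#'   vector, one entry per night.
#' @param n_sites number of sites.
#' @param n_nights number of nights when `p` is scalar.
#' @param seed optional RNG seed.
#' @return 0/1 matrix (`n_sites` x nights) of class `detection_history`,
#'   with the latent `z` attached as attribute `"z"`.
#' @export
simulate_detection_history <- function(psi, p, n_sites, n_nights = NULL,
                                       seed = NULL) {
  if (psi < 0 || psi > 1) stop("psi outside [0,1]")
  if (any(p < 0 | p > 1)) stop("p outside [0,1]")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (length(p) == 1) {
    if (is.null(n_nights)) stop("n_nights required for scalar p")
    p <- rep(p, n_nights)
  }
  if (!is.null(seed)) set.seed(seed)
  T_max <- length(p)
  z <- rbinom(n_sites, 1, psi)
  y <- matrix(rbinom(n_sites * T_max, 1, rep(z, T_max) *
                       rep(p, each = n_sites)),
              n_sites, T_max)
  dimnames(y) <- list(sprintf("S%05d", seq_len(n_sites)),
                      paste0("night_", seq_len(T_max)))
  structure(y, z = z, class = c("detection_history", "matrix"))
}

#' Simulate point-centre-quarter burrow distances
#'
#' Draws the nearest-burrow distance in each quadrant from the
#' distribution of the nearest point of a homogeneous Poisson field of the
#' given intensity restricted to a quarter-plane
#' (CDF `1 - exp(-intensity * pi * d^2 / 4)`), truncated: distances beyond
#' `truncation` are recorded as `NA` ("none found").
#'
#' @param intensity burrows per square metre (>= 0).
#' @param n_sites number of sample points.
#' @param truncation search radius in metres (default 40).
#' @param seed optional RNG seed.
#' @param burrow_type label carried into the output table.
#' @return Data frame (site_id, quadrant, burrow_type, distance_m).
#' @export
simulate_pcq <- function(intensity, n_sites, truncation = 40, seed = NULL,
                         burrow_type = "shearwater") {
  if (intensity < 0) stop("intensity must be >= 0")
  if (truncation <= 0) stop("truncation must be > 0")
  if (!is.null(seed)) set.seed(seed)
  site_ids <- sprintf("S%05d", seq_len(n_sites))
  pcq_distances(rep(intensity, n_sites), site_ids, burrow_type, truncation)
}

#' Write a simulated study bundle to disk
#'
#' @param study a `rodent_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written: triggers.csv, deployments.csv,
#'   pcq.csv, poles.csv, covers.csv, truth.json.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "rodent_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    triggers = file.path(dir, "triggers.csv"),
    deployments = file.path(dir, "deployments.csv"),
    pcq = file.path(dir, "pcq.csv"),
    poles = file.path(dir, "poles.csv"),
    covers = file.path(dir, "covers.csv"),
    truth = file.path(dir, "truth.json")
  )
  write.csv(study$triggers, paths["triggers"], row.names = FALSE)
  write.csv(study$deployments, paths["deployments"], row.names = FALSE)
  write.csv(study$habitat$pcq, paths["pcq"], row.names = FALSE)
  write.csv(study$habitat$poles, paths["poles"], row.names = FALSE)
  write.csv(study$habitat$covers, paths["covers"], row.names = FALSE)
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' @export
print.rodent_study <- function(x, ...) {
  cat("Simulated camera-trap study:", x$config$n_sites, "sites,",
      paste(range(rep(x$config$nights_per_site,
                      length.out = x$config$n_sites)), collapse = "-"),
      "nights\n")
  cat("  species:", paste(names(x$config$species_params), collapse = ", "),
      "\n")
  cat("  triggers:", nrow(x$triggers), "\n")
  invisible(x)
}
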