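# in-code fixtures shared across test files

utc <- function(x) as.POSIXct(x, tz = "UTC")

# deployment log: n sites, `nights` survey nights each, cameras set at
# `start` (afternoon) and retrieved at the noon ending the last night
make_deployments <- function(n = 3, nights = 8,
                             start = "2012-04-15 16:00:00") {
  s <- utc(start)
  anchor <- utc(format(s, "%Y-%m-%d 12:00:00"))
  if (anchor > s) anchor <- anchor - 86400
  data.frame(site_id = sprintf("S%02d", seq_len(n)),
             start = rep(s, n),
             end = rep(anchor + nights * 86400, n),
             stringsAsFactors = FALSE)
}

# trigger records at given offsets (in hours) from deployment start
make_triggers <- function(site, hours, species = "black rat",
                          start = "2012-04-15 16:00:00") {
  data.frame(site_id = site,
             timestamp = utc(start) + hours * 3600,
             species = species, stringsAsFactors = FALSE)
}

# small event table builder
make_events <- function(site_id, species, night, interval) {
  data.frame(site_id = site_id, species = species, night = night,
             interval = interval, stringsAsFactors = FALSE)
}

# write a trigger CSV and return the path
write_trigger_csv <- function(df, path = tempfile(fileext = ".csv")) {
  out <- df
  if (inherits(out$timestamp, "POSIXct")) {
    out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  }
  write.csv(out, path, row.names = FALSE)
  path
}

# independent brute-force oracle for the occupancy likelihood: explicit
# enumeration over the latent occupancy state of each site
occupancy_loglik_oracle <- function(psi, p, histories) {
  p <- rep(p, length.out = ncol(histories))
  ll <- 0
  for (i in seq_len(nrow(histories))) {
    y <- histories[i, ]
    L_site <- 0
    for (z in 0:1) {
      pr_z <- if (z == 1) psi else 1 - psi
      pr_y <- 1
      for (t in seq_along(y)) {
        if (is.na(y[t])) next
        pd <- z * p[t]  # detection prob given state
        pr_y <- pr_y * (if (y[t] == 1) pd else 1 - pd)
      }
      L_site <- L_site + pr_z * pr_y
    }
    ll <- ll + log(L_site)
  }
  ll
}

# exhaustive grid-search oracle for the constant-detection MLE: the
# site likelihood psi * p^a (1-p)^b + (1-psi) * [no detections] is
# evaluated on the full (psi, p) grid directly from its definition
occupancy_grid_oracle <- function(histories, step = 1e-3) {
  a <- rowSums(histories == 1, na.rm = TRUE)
  b <- rowSums(histories == 0, na.rm = TRUE)
  never <- as.numeric(a == 0)
  grid <- seq(step, 1 - step, by = step)
  best <- c(psi = NA, p = NA, ll = -Inf)
  for (p in grid) {
    cond <- p^a * (1 - p)^b
    ll <- colSums(log(outer(cond, grid) + outer(never, 1 - grid)))
    j <- which.max(ll)
    if (ll[j] > best["ll"]) best <- c(psi = grid[j], p = p, ll = ll[j])
  }
  best
}

# printed detection-model comparison (black rat & house mouse): -2LL and
# K for the night-varying and constant structures
printed_detection_rows <- function() {
  data.frame(
    species = rep(c("black rat", "house mouse"), each = 2),
    model = rep(c("psi(.)p(night)", "psi(.)p(.)"), 2),
    K = c(12, 2, 12, 2),
    minus2LL = c(2577.08, 2627.84, 2191.64, 2239.78),
    criterion = c(2601.08, 2631.84, 2215.64, 2243.78),
    delta = c(0, 30.76, 0, 28.14)
  )
}

# printed candidate-set delta-AICc columns for the activity GLMs
printed_delta_rat <- c(0, 2.06, 3.95, 10.19, 14.30, 15.86, 16.04, 16.26,
                       16.32, 17.59, 19.52, 19.99)
printed_delta_mouse <- c(0, 0.72, 2.00, 2.77, 3.07, 3.31, 3.97, 4.06,
                         4.81, 4.87, 5.00, 5.11, 6.71)

# fabricate a minimal nb_fit-like object for ic_table tests
fake_fit <- function(name, logLik, K) {
  structure(list(spec = list(name = name), name = name,
                 coefficients = numeric(), se = numeric(),
                 theta = 1, logLik = logLik, K = K, n = 100,
                 converged = TRUE, fit = NULL),
            class = "nb_fit")
}
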