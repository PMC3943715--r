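#' @name events
#' @title From camera triggers to events, activity indices and detection
#'   histories
#' @description A camera "trigger" is one motion activation (a burst of
#'   photos). Triggers are collapsed into discrete presence *events*: one
#'   event per species per clock-aligned 15-min interval per survey night,
#'   however many triggers fell inside it. Events per night, averaged over
#'   the nights a camera was active, give the site's activity index;
#'   any-event-per-night gives the binary detection history used for
#'   occupancy modelling.
NULL

parse_iso8601 <- function(x) {
  x <- sub("Z$", "", sub("T", " ", x))
  as.POSIXct(x, tz = "UTC",
             format = if (any(grepl("\\.", x))) "%Y-%m-%d %H:%M:%OS"
                      else "%Y-%m-%d %H:%M:%S")
}

#' Load trigger-level camera records
#'
#' @param path CSV with columns `site_id`, `timestamp` (ISO-8601, local
#'   time treated as UTC), `species`.
#' @param aliases optional named character vector mapping raw species
#'   labels (lower-cased, trimmed) to canonical names, e.g.
#'   `c("rattus rattus" = "black rat")`.
#' @return Data frame of parsed records sorted by site then timestamp.
#'   Rows with unparseable timestamps are excluded; their 1-based data
#'   line numbers are reported in a warning and attached as attribute
#'   `"excluded_lines"`.
#' @export
load_trigger_records <- function(path, aliases = NULL) {
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("site_id", "timestamp", "species")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("trigger file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    warning("trigger file has a header but no rows: ", path)
    out <- data.frame(site_id = character(), timestamp = parse_iso8601(character()),
                      species = character(), stringsAsFactors = FALSE)
    attr(out, "excluded_lines") <- integer()
    return(out)
  }
  ts <- parse_iso8601(raw$timestamp)
  bad <- which(is.na(ts))
  if (length(bad)) {
    warning(length(bad), " record(s) with unparseable timestamps excluded ",
            "(data line ", paste(bad, collapse = ", "), ")")
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  species <- raw$species[keep]
  if (!is.null(aliases)) {
    key <- tolower(trimws(species))
    hit <- key %in% names(aliases)
    species[hit] <- unname(aliases[key[hit]])
  }
  out <- data.frame(site_id = raw$site_id[keep], timestamp = ts[keep],
                    species = species, stringsAsFactors = FALSE)
  out <- out[order(out$site_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_lines") <- bad
  out
}

#' Load a deployment log
#'
#' @param path CSV with columns `site_id`, `start`, `end` (ISO-8601).
#' @return Data frame with POSIXct `start`/`end`, one row per site.
#' @export
load_deployments <- function(path) {
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("site_id", "start", "end")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("deployment file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$site_id)) {
    stop("duplicate site_id in deployment log")
  }
  data.frame(site_id = raw$site_id, start = parse_iso8601(raw$start),
             end = parse_iso8601(raw$end), stringsAsFactors = FALSE)
}

#' Assign survey nights and 15-min intervals to trigger records
#'
#' Survey nights run noon-to-noon (local time) so a nocturnal animal's
#' activity falls within a single night; night 1 starts at the noon
#' boundary at or before the site's deployment start. Intervals are the
#' 96 clock-aligned 15-min bins of each night (index 0-95).
#'
#' @param records trigger records (from [load_trigger_records()] or
#'   in-memory with POSIXct `timestamp`).
#' @param deployments deployment log with POSIXct `start`/`end`.
#' @return `records` with `night` and `interval` columns; records outside
#'   their site's deployment window are dropped, with the count attached
#'   as attribute `"n_outside_deployment"`.
#' @export
assign_survey_nights <- function(records, deployments) {
  unknown <- setdiff(unique(records$site_id), deployments$site_id)
  if (length(unknown)) {
    stop("site_id(s) not in deployment log: ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(records$site_id, deployments$site_id)
  dep_start <- deployments$start[idx]
  dep_end <- deployments$end[idx]
  inside <- records$timestamp >= dep_start & records$timestamp <= dep_end
  n_out <- sum(!inside)
  if (n_out) {
    message(n_out, " record(s) outside their deployment window dropped")
  }
  records <- records[inside, , drop = FALSE]
  anchor <- noon_before(dep_start[inside])
  secs <- as.numeric(difftime(records$timestamp, anchor, units = "secs"))
  records$night <- as.integer(secs %/% 86400) + 1L
  records$interval <- as.integer((secs %% 86400) %/% 900)
  rownames(records) <- NULL
  attr(records, "n_outside_deployment") <- n_out
  records
}

#' Collapse triggers into 15-minute presence events
#'
#' One event per distinct (site, species, night, interval) combination,
#' regardless of how many triggers fell inside the interval.
#'
#' @param records trigger records with `night` and `interval` assigned.
#' @return Event table data frame (site_id, species, night, interval),
#'   sorted; also records `n_triggers` per event.
#' @export
discretize_events <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(site_id = character(), species = character(),
                      night = integer(), interval = integer(),
                      n_triggers = integer(), stringsAsFactors = FALSE))
  }
  if (is.null(records$night) || is.null(records$interval)) {
    stop("records need night/interval; run assign_survey_nights() first")
  }
  key <- interaction(records$site_id, records$species, records$night,
                     records$interval, drop = TRUE)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  first <- records[!duplicated(key), c("site_id", "species", "night",
                                       "interval")]
  first$n_triggers <- agg$Freq[match(as.character(key[!duplicated(key)]),
                                     agg$key)]
  first <- first[order(first$site_id, first$species, first$night,
                       first$interval), , drop = FALSE]
  rownames(first) <- NULL
  first
}

# nights covered (integer count) and fractional nights for each deployment
deployment_nights <- function(deployments) {
  anchor <- noon_before(deployments$start)
  dur <- as.numeric(difftime(deployments$end, deployments$start,
                             units = "days"))
  n_int <- ceiling(as.numeric(difftime(deployments$end, anchor,
                                       units = "days")) - 1e-9)
  data.frame(site_id = deployments$site_id, nights_frac = dur,
             nights_int = as.integer(n_int), stringsAsFactors = FALSE)
}

#' Per-site activity index (events per 24 h)
#'
#' @param events event table from [discretize_events()].
#' @param deployments deployment log with POSIXct `start`/`end`.
#' @param species optional species subset; default: all species in
#'   `events`.
#' @param nights_mode `"fractional"` (default) divides by the exact
#'   deployment duration in days; `"integer"` divides by the number of
#'   survey nights the deployment touched.
#' @return Data frame (site_id, species, events_total, nights_observed,
#'   index), one row per site x species, zero-event sites included.
#' @export
activity_index <- function(events, deployments, species = NULL,
                           nights_mode = c("fractional", "integer")) {
  nights_mode <- match.arg(nights_mode)
  dn <- deployment_nights(deployments)
  if (any(dn$nights_frac <= 0)) {
    stop("deployment with zero or negative duration: ",
         paste(dn$site_id[dn$nights_frac <= 0], collapse = ", "))
  }
  if (is.null(species)) species <- sort(unique(events$species))
  if (length(species) == 0) species <- character()
  grid <- expand.grid(site_id = dn$site_id, species = species,
                      stringsAsFactors = FALSE)
  ev <- events[events$species %in% species, , drop = FALSE]
  cnt <- if (nrow(ev)) {
    stats::aggregate(list(events_total = rep(1L, nrow(ev))),
                     by = ev[c("site_id", "species")], FUN = sum)
  } else {
    data.frame(site_id = character(), species = character(),
               events_total = integer(), stringsAsFactors = FALSE)
  }
  out <- merge(grid, cnt, by = c("site_id", "species"), all.x = TRUE)
  out$events_total[is.na(out$events_total)] <- 0L
  nts <- if (nights_mode == "fractional") dn$nights_frac else dn$nights_int
  out$nights_observed <- nts[match(out$site_id, dn$site_id)]
  out$index <- out$events_total / out$nights_observed
  out <- out[order(out$species, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nightly detection histories for one species
#'
#' @param events event table from [discretize_events()].
#' @param deployments deployment log with POSIXct `start`/`end`.
#' @param species species label; if absent from the events the histories
#'   are all zeros.
#' @return 0/1/NA matrix (sites x nights, class `detection_history`):
#'   1 if the species had >= 1 event that site-night, 0 if the night was
#'   surveyed without an event, NA for nights outside the deployment.
#' @export
detection_histories <- function(events, deployments, species) {
  dn <- deployment_nights(deployments)
  T_max <- max(dn$nights_int)
  y <- matrix(NA_real_, nrow(dn), T_max,
              dimnames = list(dn$site_id, paste0("night_", seq_len(T_max))))
  for (i in seq_len(nrow(dn))) y[i, seq_len(dn$nights_int[i])] <- 0
  ev <- events[events$species == species & events$night <= T_max, ,
               drop = FALSE]
  if (nrow(ev)) {
    ij <- cbind(match(ev$site_id, dn$site_id), ev$night)
    y[ij] <- 1
  }
  structure(y, species = species, class = c("detection_history", "matrix"))
}

#' Naive occupancy of a detection history
#'
#' Fraction of sites with at least one detection: a lower bound on the
#' occupancy probability psi.
#'
#' @param histories `detection_history` matrix.
#' @return Numeric scalar in \[0,1\].
#' @export
naive_occupancy <- function(histories) {
  mean(apply(histories, 1, function(r) any(r == 1, na.rm = TRUE)))
}
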