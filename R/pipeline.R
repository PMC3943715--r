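#' @name cli_report
#' @title Pipeline orchestration and summary tables
#' @description [run_pipeline()] drives the full analysis from a single
#'   config — events, occupancy, habitat covariates, candidate-set GLMs —
#'   and writes every summary table as CSV plus a run manifest, so a
#'   report is regenerated identically from the same inputs.
NULL

#' Build a pipeline configuration
#'
#' @param triggers,deployments,pcq,poles,covers input CSV paths; or pass
#'   a simulated bundle via `study` instead.
#' @param study optional `rodent_study` object (overrides the paths).
#' @param focal list describing the focal species; each element is a list
#'   with `label` (species label in the trigger table), `set` (candidate
#'   set name for [candidate_sets()]) and optionally `rr_from` (species
#'   whose activity index enters as the `RR` covariate).
#' @param species_aliases optional alias map for [load_trigger_records()].
#' @param level confidence level for nights-to-absence.
#' @param criterion `"aicc"` or `"aic"`.
#' @param average_below top-weight threshold triggering model averaging.
#' @param nights_mode `"fractional"` or `"integer"` activity denominators.
#' @param out output directory.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(triggers = NULL, deployments = NULL,
                            pcq = NULL, poles = NULL, covers = NULL,
                            study = NULL,
                            focal = list(
                              list(label = "black rat", set = "black_rat"),
                              list(label = "house mouse",
                                   set = "house_mouse",
                                   rr_from = "black rat")),
                            species_aliases = NULL,
                            level = 0.95,
                            criterion = c("aicc", "aic"),
                            average_below = 0.9,
                            nights_mode = "fractional",
                            out = tempfile("rodentcam_run_"),
                            seed = 1L) {
  criterion <- match.arg(criterion)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  if (is.null(study)) {
    paths <- c(triggers = triggers, deployments = deployments, pcq = pcq,
               poles = poles, covers = covers)
    if (length(paths) < 5) stop("supply all five input paths or a study")
    bad <- paths[!file.exists(paths)]
    if (length(bad)) {
      stop("input file(s) not found: ", paste(bad, collapse = ", "))
    }
  }
  structure(list(triggers = triggers, deployments = deployments,
                 pcq = pcq, poles = poles, covers = covers, study = study,
                 focal = focal, species_aliases = species_aliases,
                 level = level, criterion = criterion,
                 average_below = average_below, nights_mode = nights_mode,
                 out = out, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(name, " stage: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes events -> occupancy -> habitat -> model selection and writes
#' all summary tables (events, activity indices, detection histories,
#' occurrence table, detection-model IC tables, detection curves,
#' covariates, GLM IC tables, averaged coefficients) under `config$out`,
#' together with `manifest.json` recording inputs, options and package
#' version.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with every computed object plus the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(...) file.path(config$out, ...)

  # ---- events stage
  ev_res <- stage("events", {
    if (!is.null(config$study)) {
      trig <- config$study$triggers
      trig$timestamp <- parse_iso8601(trig$timestamp)
      dep <- config$study$deployments
      dep$start <- parse_iso8601(dep$start)
      dep$end <- parse_iso8601(dep$end)
    } else {
      trig <- load_trigger_records(config$triggers, config$species_aliases)
      dep <- load_deployments(config$deployments)
    }
    trig <- assign_survey_nights(trig, dep)
    events <- discretize_events(trig)
    act <- activity_index(events, dep, nights_mode = config$nights_mode)
    occ_tab <- species_occurrence_table(events, dep)
    write.csv(events, outfile("events.csv"), row.names = FALSE)
    write.csv(act, outfile("activity.csv"), row.names = FALSE)
    write.csv(occ_tab, outfile("species_occurrence.csv"),
              row.names = FALSE)
    list(deployments = dep, events = events, activity = act,
         occurrence = occ_tab)
  })

  # ---- occupancy stage (per focal species)
  occ_res <- stage("occupancy", {
    lapply(config$focal, function(fs) {
      hist <- detection_histories(ev_res$events, ev_res$deployments,
                                  fs$label)
      write.csv(data.frame(site_id = rownames(hist), hist,
                           check.names = FALSE),
                outfile(paste0("history_", gsub(" ", "_", fs$label),
                               ".csv")), row.names = FALSE)
      fits <- list(
        "psi(.)p(.)" = fit_occupancy(hist, "constant"),
        "psi(.)p(night)" = fit_occupancy(hist, "by_night")
      )
      cmp <- compare_detection_models(fits, criterion = config$criterion)
      best <- fits[[cmp$model[1]]]
      curve <- cumulative_detection(best$p, lower = best$p_ci[, 1],
                                    upper = best$p_ci[, 2])
      ntc <- nights_to_confidence(best$p, level = config$level)
      slug <- gsub(" ", "_", fs$label)
      write.csv(as.data.frame(cmp),
                outfile(paste0("detection_models_", slug, ".csv")),
                row.names = FALSE)
      write.csv(as.data.frame(curve),
                outfile(paste0("detection_curve_", slug, ".csv")),
                row.names = FALSE)
      jsonlite::write_json(
        list(species = fs$label, psi = best$psi, psi_se = best$psi_se,
             p = best$p, p_se = best$p_se, logLik = best$logLik,
             K = best$K, nights_to_confidence = ntc),
        outfile(paste0("occupancy_", slug, ".json")),
        auto_unbox = TRUE, digits = NA)
      list(species = fs$label, histories = hist, fits = fits,
           comparison = cmp, curve = curve, nights = ntc)
    })
  })

  # ---- habitat stage
  hab_res <- stage("habitat", {
    if (!is.null(config$study)) {
      h <- config$study$habitat
      covs <- assemble_covariates(h$pcq, h$poles, h$covers)
    } else {
      covs <- assemble_covariates(read.csv(config$pcq),
                                  read.csv(config$poles),
                                  read.csv(config$covers))
    }
    write.csv(covs, outfile("covariates.csv"), row.names = FALSE)
    covs
  })

  # ---- model-selection stage
  glm_res <- stage("model_selection", {
    act_wide <- ev_res$activity
    lapply(config$focal, function(fs) {
      a <- act_wide[act_wide$species == fs$label, ]
      dat <- merge(a, hab_res, by = "site_id")
      if (!is.null(fs$rr_from)) {
        rr <- act_wide[act_wide$species == fs$rr_from,
                       c("site_id", "index")]
        names(rr)[2] <- "RR"
        dat <- merge(dat, rr, by = "site_id")
      }
      sel <- select_models(candidate_sets(fs$set), dat,
                           criterion = config$criterion,
                           average_below = config$average_below)
      slug <- gsub(" ", "_", fs$label)
      write.csv(as.data.frame(sel$table),
                outfile(paste0("glm_ic_", slug, ".csv")),
                row.names = FALSE)
      if (!is.null(sel$averaged)) {
        write.csv(sel$averaged,
                  outfile(paste0("glm_averaged_", slug, ".csv")),
                  row.names = FALSE)
      }
      sel
    })
  })

  manifest <- list(
    package = "rodentcam",
    version = as.character(utils::packageVersion("rodentcam")),
    seed = config$seed,
    options = list(level = config$level, criterion = config$criterion,
                   average_below = config$average_below,
                   nights_mode = config$nights_mode),
    inputs = if (is.null(config$study))
      list(triggers = config$triggers, deployments = config$deployments,
           pcq = config$pcq, poles = config$poles, covers = config$covers)
      else "in-memory simulated study",
    outputs = list.files(config$out)
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(events = ev_res, occupancy = occ_res,
                 covariates = hab_res, models = glm_res,
                 out = config$out))
}

#' Species site-occurrence summary
#'
#' One row per species: number of sites where it was recorded, that count
#' as a percentage of all surveyed sites (rounded half-up to the nearest
#' integer, with the raw proportion also reported) and the total number
#' of 15-min events.
#'
#' @param events event table from [discretize_events()].
#' @param deployments deployment log (defines the site total).
#' @return Data frame (species, sites_present, pct_sites, prop_sites,
#'   n_events) sorted by decreasing occurrence.
#' @export
species_occurrence_table <- function(events, deployments) {
  total <- length(unique(deployments$site_id))
  if (total == 0) stop("deployment log has no sites")
  sp <- sort(unique(events$species))
  if (length(sp) == 0) {
    return(data.frame(species = character(), sites_present = integer(),
                      pct_sites = numeric(), prop_sites = numeric(),
                      n_events = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(sp, function(s) {
    e <- events[events$species == s, ]
    ns <- length(unique(e$site_id))
    data.frame(species = s, sites_present = ns,
               pct_sites = round_half_up(100 * ns / total),
               prop_sites = ns / total,
               n_events = nrow(e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$sites_present, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}
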