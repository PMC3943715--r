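test_that("trigger CSVs load, report and exclude malformed rows", {
  good <- make_triggers("S01", c(1, 2, 3))
  expect_equal(nrow(load_trigger_records(write_trigger_csv(good))), 3)

  bad <- good
  bad$timestamp <- format(bad$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  bad <- rbind(bad, data.frame(site_id = "S01", timestamp = "not-a-time",
                               species = "black rat"))
  expect_warning(rec <- load_trigger_records(write_trigger_csv(bad)),
                 "unparseable")
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "excluded_lines"), 4L)

  empty <- good[0, ]
  expect_warning(rec0 <- load_trigger_records(write_trigger_csv(empty)),
                 "no rows")
  expect_equal(nrow(rec0), 0)

  noc <- data.frame(site = "S01", when = "2012-04-15T17:00:00Z")
  p <- tempfile(fileext = ".csv"); write.csv(noc, p, row.names = FALSE)
  expect_error(load_trigger_records(p), "missing column")
})

test_that("species aliases normalize labels before counting", {
  trig <- make_triggers("S01", 1:2, species = c("Rattus rattus", "black rat"))
  p <- write_trigger_csv(trig)
  rec <- load_trigger_records(p, aliases = c("rattus rattus" = "black rat"))
  expect_equal(unique(rec$species), "black rat")
})

test_that("survey nights follow noon-to-noon boundaries", {
  dep <- make_deployments(1, nights = 8)  # starts 16:00
  cases <- make_triggers("S01", c(
    2,        # 18:00 day 0 -> night 1
    19 + 59/60,  # 11:59 next day -> night 1
    20 + 1/60,   # 12:01 next day -> night 2
    7 * 24 + 18  # 10:00 on the final morning -> night 8
  ))
  out <- assign_survey_nights(cases, dep)
  expect_equal(out$night, c(1L, 1L, 2L, 8L))

  # outside the window: before start or after retrieval noon
  outside <- make_triggers("S01", c(-1, 8 * 24))
  expect_message(dropped <- assign_survey_nights(outside, dep), "dropped")
  expect_equal(nrow(dropped), 0)

  unknown <- make_triggers("S99", 1)
  expect_error(assign_survey_nights(unknown, dep), "S99")
})

test_that("triggers collapse to clock-aligned 15-min events", {
  dep <- make_deployments(1)
  # five triggers 02:01-02:13 (one bin) and triggers at 02:14 and 02:16
  # (bin boundary at 02:15): 10h after the 16:00 start is 02:00
  h5 <- 10 + c(1, 4, 7, 10, 13) / 60
  h2 <- 10 + c(14, 16) / 60
  ev1 <- discretize_events(assign_survey_nights(
    make_triggers("S01", h5), dep))
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$n_triggers, 5L)
  ev2 <- discretize_events(assign_survey_nights(
    make_triggers("S01", h2), dep))
  expect_equal(nrow(ev2), 2)
  expect_equal(nrow(discretize_events(make_triggers("S01", 1)[0, ])), 0)
})

test_that("event discretization is order-invariant and conserves counts", {
  set.seed(21)
  hrs <- sort(runif(60, 0, 7 * 24))
  trig <- make_triggers("S01", hrs)
  dep <- make_deployments(1)
  ev <- discretize_events(assign_survey_nights(trig, dep))
  shuffled <- trig[sample(nrow(trig)), ]
  ev2 <- discretize_events(assign_survey_nights(shuffled, dep))
  expect_identical(ev, ev2)
  # conservation: per-night counts sum to the total distinct bins
  per_night <- table(ev$night)
  expect_equal(sum(per_night), nrow(unique(ev[c("night", "interval")])))
})

test_that("activity index is events per 24 h with zero-event sites kept", {
  dep <- make_deployments(2, nights = 8, start = "2012-04-15 12:00:00")
  # 31 events in night 1 at S01 (the observed maximum: 31 events/night)
  ev <- make_events("S01", "black rat", 1L, as.integer(seq(0, 90, 3)))
  one_night_dep <- make_deployments(1, nights = 1,
                                    start = "2012-04-15 12:00:00")
  ai <- activity_index(ev, one_night_dep)
  expect_equal(ai$index, 31)

  # 1 event over 8 nights: the reported house-mouse median of 0.125
  ev8 <- make_events("S01", "house mouse", 3L, 10L)
  ai8 <- activity_index(ev8, dep)
  expect_equal(ai8$index[ai8$site_id == "S01"], 0.125)
  expect_equal(ai8$index[ai8$site_id == "S02"], 0)
  expect_equal(ai8$nights_observed, c(8, 8))

  bad_dep <- data.frame(site_id = "S01",
                        start = utc("2012-04-15 12:00:00"),
                        end = utc("2012-04-15 12:00:00"))
  expect_error(activity_index(ev, bad_dep), "zero")
})

test_that("fractional nights divide partial deployments correctly", {
  dep <- make_deployments(1, nights = 8)  # 16:00 start -> 7 + 20/24 days
  ev <- make_events("S01", "black rat", 1L, 20L)
  frac <- activity_index(ev, dep, nights_mode = "fractional")
  expect_equal(frac$nights_observed, 8 - 4 / 24)
  int <- activity_index(ev, dep, nights_mode = "integer")
  expect_equal(int$nights_observed, 8)
  expect_equal(int$index, 1 / 8)
})

test_that("detection histories mark nights and missingness correctly", {
  dep <- make_deployments(2, nights = 8)
  ev <- make_events("S01", "black rat", c(1L, 3L), c(5L, 40L))
  h <- detection_histories(ev, dep, "black rat")
  expect_equal(unname(h["S01", ]), c(1, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(h["S02", ]), rep(0, 8))

  # ragged: one site deployed 6 of 11 study nights
  dep2 <- rbind(make_deployments(1, nights = 11),
                within(make_deployments(1, nights = 6),
                       site_id <- "S02"))
  h2 <- detection_histories(ev, dep2, "black rat")
  expect_equal(sum(is.na(h2["S02", ])), 5)
  expect_equal(sum(!is.na(h2["S02", ])), 6)

  # unknown species: all-zero histories, never NA inside deployment
  h3 <- detection_histories(ev, dep, "feral cat")
  expect_true(all(h3 == 0))
})

test_that("naive occupancy equals the fraction of sites with events", {
  st <- simulate_study(study_config(n_sites = 30, nights_per_site = 5,
                                    seed = 8))
  trig <- st$triggers
  trig$timestamp <- rodentcam:::parse_iso8601(trig$timestamp)
  dep <- st$deployments
  dep$start <- rodentcam:::parse_iso8601(dep$start)
  dep$end <- rodentcam:::parse_iso8601(dep$end)
  ev <- discretize_events(assign_survey_nights(trig, dep))
  for (sp in c("black rat", "house mouse")) {
    h <- detection_histories(ev, dep, sp)
    frac <- length(unique(ev$site_id[ev$species == sp])) / 30
    expect_equal(naive_occupancy(h), frac)
    expect_lte(naive_occupancy(h), 1)
  }
})
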