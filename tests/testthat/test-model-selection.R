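test_that("information criteria reproduce printed detection-table arithmetic", {
  rows <- printed_detection_rows()
  # criterion = -2LL + 2K for every printed row
  expect_equal(aic(-rows$minus2LL / 2, rows$K), rows$criterion)
  expect_equal(aic(0, 0), 0)
  # small-sample correction vanishes as n grows
  expect_lt(abs(aicc(-100, 5, 1e8) - aic(-100, 5)), 1e-6)
  expect_equal(aicc(-100, 3, 50), aic(-100, 3) + 2 * 3 * 4 / 46)
  expect_error(aicc(-100, 5, 6), "n > K")
})

test_that("akaike weights normalize, rebase-invariantly", {
  expect_equal(akaike_weights(0), 1)
  expect_error(akaike_weights(numeric()), "empty")
  set.seed(43)
  for (i in 1:20) {
    d <- runif(6, 0, 30)
    w <- akaike_weights(d)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(akaike_weights(d + 7.3), w, tolerance = 1e-12)
  }
})

test_that("printed candidate-set deltas reproduce the published weights", {
  w_rat <- akaike_weights(printed_delta_rat)
  expect_equal(round(w_rat[1], 3), 0.665)
  w_mouse <- akaike_weights(printed_delta_mouse)
  expect_equal(round(w_mouse[1], 3), 0.297)
  expect_equal(round(w_mouse[2], 3), 0.207)
})

test_that("ic tables sort, weight and guard their inputs", {
  f1 <- fake_fit("A", -100, 3)
  f2 <- fake_fit("B", -100, 3)
  tab <- ic_table(list(f1, f2), n = 100)
  expect_equal(tab$weight, c(0.5, 0.5))

  # a 30.76-point gap: weights 1.00 / 0.00 at two decimals
  g1 <- fake_fit("night", -2577.08 / 2, 12)
  g2 <- fake_fit("const", -2627.84 / 2, 2)
  tab2 <- ic_table(list(g1, g2), n = 276, criterion = "aic")
  expect_equal(tab2$delta, c(0, 30.76))
  expect_equal(round(tab2$weight, 2), c(1, 0))

  expect_error(ic_table(list(f1, fake_fit("A", -90, 2)), n = 100),
               "duplicate")
  expect_error(ic_table(list(), n = 100), "no fits")

  # random fits: ordering matches an independent resort, weights sum to 1
  set.seed(47)
  fits <- lapply(1:8, function(i) {
    fake_fit(paste0("M", i), -runif(1, 50, 150), sample(2:6, 1))
  })
  tab3 <- ic_table(fits, n = 60, criterion = "aicc")
  ll <- vapply(fits, function(f) f$logLik, numeric(1))
  K <- vapply(fits, function(f) f$K, numeric(1))
  expect_equal(tab3$model,
               paste0("M", 1:8)[order(aicc(ll, K, 60))])
  expect_equal(sum(tab3$weight), 1, tolerance = 1e-12)
})

test_that("candidate sets match the a-priori design", {
  rat <- candidate_sets("black_rat")
  expect_length(rat, 12)
  expect_equal(rat[[1]]$name, "C_gt1m")
  mouse <- candidate_sets("house_mouse")
  expect_length(mouse, 13)
  expect_true("RR" %in% vapply(mouse, function(s) s$name, character(1)))
  # hierarchy: every interaction's mains are present
  for (s in c(rat, mouse)) {
    for (ia in s$interactions) expect_true(all(ia %in% s$terms))
  }
  expect_error(candidate_sets("cat"))
  expect_error(model_spec("bad", "a", list(c("a", "b"))), "main effects")
})

test_that("intercept-only nb fit recovers the closed-form rate", {
  dat <- data.frame(events_total = rep(12L, 40), nights_observed = 8)
  f <- fit_nb_glm(model_spec("Constant"), dat)
  expect_equal(unname(coef(f$fit)[1]), log(12 / 8), tolerance = 1e-6)
  expect_equal(f$K, 2)
  expect_error(fit_nb_glm(model_spec("Constant"),
                          data.frame(events_total = c(1.5, 2),
                                     nights_observed = 1)),
               "integer")
  expect_error(fit_nb_glm(model_spec("X", "X"), dat), "missing from data")
})

test_that("nb fit approaches the Poisson fit when data are equidispersed", {
  set.seed(51)
  n <- 300
  x <- rnorm(n)
  mu <- exp(1 + 0.4 * x) * 5
  dat <- data.frame(events_total = rpois(n, mu), nights_observed = 5,
                    x = x)
  # dispersion fixed at a huge value: the exact Poisson limit
  nb_lim <- fit_nb_glm(model_spec("x", "x"), dat, theta = 1e8)
  po <- glm(events_total ~ x + offset(log(nights_observed)),
            poisson, dat)
  expect_equal(unname(nb_lim$coefficients), unname(coef(po)),
               tolerance = 1e-6)
  # profiled dispersion drifts very large and coefficients follow
  nb <- fit_nb_glm(model_spec("x", "x"), dat)
  expect_gt(nb$theta, 500)
  expect_equal(unname(nb$coefficients), unname(coef(po)), tolerance = 1e-3)
})

test_that("nb fit recovers simulated effects with nominal coverage", {
  set.seed(57)
  b0 <- 1.0; b1 <- 0.5; theta <- 2
  hits <- logical(150)
  est <- numeric(150)
  for (r in seq_len(150)) {
    x <- rnorm(276)
    mu <- exp(b0 + b1 * x) * 8
    dat <- data.frame(events_total = rnbinom(276, size = theta, mu = mu),
                      nights_observed = 8, x = x)
    f <- fit_nb_glm(model_spec("x", "x"), dat)
    est[r] <- f$coefficients[["x"]]
    ci <- f$coefficients[["x"]] + c(-1.96, 1.96) * f$se[["x"]]
    hits[r] <- ci[1] <= b1 && b1 <= ci[2]
  }
  expect_equal(mean(est), b1, tolerance = 0.02)
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("adding a covariate never decreases the maximized likelihood", {
  set.seed(59)
  x <- rnorm(120); z <- rnorm(120)
  dat <- data.frame(events_total = rnbinom(120, size = 1,
                                           mu = exp(1 + 0.5 * x) * 4),
                    nights_observed = 4, x = x, z = z)
  f0 <- fit_nb_glm(model_spec("Constant"), dat)
  f1 <- fit_nb_glm(model_spec("x", "x"), dat)
  f2 <- fit_nb_glm(model_spec("x+z", c("x", "z")), dat)
  expect_gte(f1$logLik, f0$logLik - 1e-6)
  expect_gte(f2$logLik, f1$logLik - 1e-6)
})

test_that("model averaging shrinks, weights and bounds correctly", {
  # three-model toy set, hand-computed weighted sums
  f1 <- fake_fit("m1", -10, 2)
  f2 <- fake_fit("m2", -11, 2)
  f3 <- fake_fit("m3", -14, 2)
  f1$coefficients <- c("(Intercept)" = 1.0, x = 0.50)
  f1$se <- c("(Intercept)" = 0.1, x = 0.20)
  f2$coefficients <- c("(Intercept)" = 0.8, x = 0.30)
  f2$se <- c("(Intercept)" = 0.1, x = 0.25)
  f3$coefficients <- c("(Intercept)" = 1.2)
  f3$se <- c("(Intercept)" = 0.1)
  tab <- ic_table(list(f1, f2, f3), n = 100, criterion = "aic")
  w <- akaike_weights(c(0, 2, 8))  # deltas from the logLik gaps
  avg <- model_average(tab, list(f1, f2, f3))
  x_bar <- w[1] * 0.5 + w[2] * 0.3  # shrinkage: 0 in m3
  expect_equal(avg$estimate[avg$term == "x"], unname(x_bar))
  se_unc <- w[1] * sqrt(0.20^2 + (0.5 - x_bar)^2) +
    w[2] * sqrt(0.25^2 + (0.3 - x_bar)^2) +
    w[3] * sqrt(0 + x_bar^2)
  expect_equal(avg$se[avg$term == "x"], unname(se_unc))
  expect_equal(avg$importance[avg$term == "x"], unname(w[1] + w[2]))
  row <- avg[avg$term == "x", ]
  expect_true(row$lower <= row$estimate & row$estimate <= row$upper)

  # identical coefficient everywhere: averaging leaves it unchanged
  f3b <- f3
  f3b$coefficients <- c("(Intercept)" = 1.2, x = 0.5)
  f3b$se <- c("(Intercept)" = 0.1, x = 0.2)
  f1b <- f1; f2b <- f2
  f1b$coefficients["x"] <- 0.5; f2b$coefficients["x"] <- 0.5
  tab_b <- ic_table(list(f1b, f2b, f3b), n = 100, criterion = "aic")
  avg_b <- model_average(tab_b, list(f1b, f2b, f3b))
  expect_equal(avg_b$estimate[avg_b$term == "x"], 0.5)

  # a term confined to a ~zero-weight model averages to ~zero
  f4 <- fake_fit("m4", -60, 2)
  f4$coefficients <- c("(Intercept)" = 1, y = 3.0)
  f4$se <- c("(Intercept)" = 0.1, y = 0.5)
  tab4 <- ic_table(list(f1, f2, f4), n = 100, criterion = "aic")
  avg4 <- model_average(tab4, list(f1, f2, f4))
  expect_lt(abs(avg4$estimate[avg4$term == "y"]), 1e-10)
})

test_that("a strong true covariate wins the candidate-set comparison", {
  # selection-consistency smoke test on data generated from the C_gt1m
  # model with a strong effect, in the small-sample regime where the
  # AICc correction actively penalises the richer nested rivals (for
  # AIC-family criteria the top-model probability against nested
  # competitors levels off around 75-80% at large n, by design)
  set.seed(63)
  wins <- 0L
  n_rep <- 150
  for (r in seq_len(n_rep)) {
    n <- 20
    covs <- data.frame(
      C_gt1m = round(100 * rbeta(n, 1.3, 3)),
      C10_40 = rgamma(n, 2, 0.5),
      Poa = runif(n, 0, 60), Tetra = runif(n, 0, 30),
      Rhag = runif(n, 0, 30),
      Atden = rexp(n, 1 / 50), Emden = rexp(n, 1 / 20)
    )
    covs$BD <- covs$Atden + covs$Emden
    mu <- exp(0.5 + 0.06 * covs$C_gt1m) * 8
    dat <- cbind(events_total = rnbinom(n, size = 3, mu = mu),
                 nights_observed = 8, covs)
    sel <- select_models(candidate_sets("black_rat"), dat,
                         average_below = 0)
    if (sel$table$model[1] == "C_gt1m") wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})
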