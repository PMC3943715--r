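#' @name occupancy
#' @title Single-season occupancy models with constant or night-varying
#'   detection
#' @description The zero-inflated Bernoulli (MacKenzie-style) likelihood:
#'   a site is occupied with probability psi; given occupancy, each
#'   surveyed night yields a detection with probability `p` (constant) or
#'   `p_t` (one parameter per night). An all-zero history can arise from
#'   an unoccupied site or an occupied one that was never detected, so
#'   per site
#'   `L_s = psi * prod_t p_t^y * (1-p_t)^(1-y) + (1-psi) * I(all y = 0)`,
#'   with unsurveyed (NA) nights skipped. Models are compared by
#'   information criteria; the fitted detection vector gives the
#'   cumulative probability of having detected an occupant after n
#'   nights, and hence the effort needed to call an absence with
#'   confidence.
NULL

#' Occupancy model log-likelihood
#'
#' @param psi occupancy probability.
#' @param p detection probability: scalar (broadcast over nights) or one
#'   value per column of `histories`.
#' @param histories 0/1/NA matrix, sites x nights (`detection_history`).
#' @return Sum over sites of the log of the zero-inflated Bernoulli
#'   site likelihood.
#' @export
occupancy_loglik <- function(psi, p, histories) {
  if (any(psi < 0 | psi > 1)) stop("psi outside [0,1]")
  if (any(p < 0 | p > 1)) stop("p outside [0,1]")
  histories <- as.matrix(histories)
  T_max <- ncol(histories)
  if (nrow(histories) == 0) stop("histories is empty")
  if (!length(p) %in% c(1L, T_max)) {
    stop("p must have length 1 or ncol(histories)")
  }
  p <- rep(p, length.out = T_max)
  P <- matrix(p, nrow(histories), T_max, byrow = TRUE)
  lt <- log(ifelse(histories == 1, P, 1 - P))  # NA nights stay NA
  cond <- exp(rowSums(lt, na.rm = TRUE))       # prod over observed nights
  n_obs <- rowSums(!is.na(histories))
  never <- rowSums(histories == 1, na.rm = TRUE) == 0
  L <- psi * cond + (1 - psi) * as.numeric(never)
  sum(log(L[n_obs > 0]))
}

# negative log-likelihood on the logit scale; theta = (qlogis(psi),
# qlogis(p_1..p_T or p))
occ_nll_logit <- function(theta, histories, by_night) {
  psi <- plogis(theta[1])
  p <- plogis(theta[-1])
  -occupancy_loglik(psi, p, histories)
}

#' Fit a single-season occupancy model
#'
#' Maximum likelihood on the logit scale (so estimates respect \[0,1\])
#' with multi-start quasi-Newton optimisation; standard errors come from
#' the inverse observed information, delta-method-transformed to the
#' probability scale, and 95% confidence intervals are Wald intervals on
#' the logit scale back-transformed.
#'
#' @param histories 0/1/NA matrix, sites x nights.
#' @param detection `"constant"` (one shared p; K = 2) or `"by_night"`
#'   (one p per night; K = nights + 1). Nights are whatever the data
#'   contain; nothing is hard-coded.
#' @param n_starts number of optimisation starts (>= 5 in total including
#'   the naive-estimate and 0.5 starts).
#' @return An `occupancy_fit`: psi/p estimates with SEs and CIs, logLik,
#'   K, n_sites, and a `convergence` flag (`"ok"`, `"boundary"` when an
#'   estimate sits at 0/1, or `"failed"`).
#' @export
fit_occupancy <- function(histories,
                          detection = c("constant", "by_night"),
                          n_starts = 5) {
  detection <- match.arg(detection)
  histories <- as.matrix(histories)
  obs <- !is.na(histories)
  if (!any(obs)) stop("no observed nights in histories")
  T_max <- ncol(histories)
  if (detection == "by_night" && T_max < 2) {
    stop("by_night detection needs >= 2 survey nights")
  }
  n_p <- if (detection == "constant") 1L else T_max
  K <- n_p + 1L

  detected <- apply(histories, 1, function(r) any(r == 1, na.rm = TRUE))
  naive_psi <- mean(detected)
  naive_p <- sum(histories == 1, na.rm = TRUE) / sum(obs)

  all_ones <- all(histories[obs] == 1)
  all_zero <- !any(detected)
  if (all_ones || all_zero) {
    # saturated / unidentifiable boundary cases: exact boundary fit
    psi_hat <- if (all_ones) 1 else 0
    p_hat <- rep(if (all_ones) 1 else 0, n_p)
    if (all_zero) {
      warning("all-zero histories: psi unidentifiable, boundary fit")
    }
    fit <- list(psi = psi_hat, p = p_hat,
                psi_se = NA_real_, p_se = rep(NA_real_, n_p),
                psi_ci = c(NA_real_, NA_real_),
                p_ci = matrix(NA_real_, n_p, 2),
                logLik = 0, K = K, n_sites = nrow(histories),
                detection = detection, T_max = T_max,
                naive_occupancy = naive_psi, convergence = "boundary")
    class(fit) <- "occupancy_fit"
    return(fit)
  }

  clamp <- function(x) pmin(pmax(x, 1e-4), 1 - 1e-4)
  starts <- list(
    qlogis(clamp(c(naive_psi, rep(naive_p, n_p)))),
    rep(0, K),                                   # all probabilities 0.5
    qlogis(clamp(c(0.2, rep(0.2, n_p)))),
    qlogis(clamp(c(0.8, rep(0.8, n_p)))),
    qlogis(clamp(c(min(naive_psi * 1.1 + 0.05, 0.99),
                   rep(naive_p * 0.8, n_p))))
  )
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1]] <- stats::rnorm(K, 0, 1.5)
  }

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, occ_nll_logit, histories = histories, by_night = n_p > 1,
            method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-10) best <- res
  }
  if (is.null(best)) {
    stop("occupancy optimisation failed from every start")
  }

  theta <- best$par
  psi_hat <- plogis(theta[1])
  p_hat <- plogis(theta[-1])
  conv <- if (best$convergence != 0) "failed"
          else if (any(abs(theta) > 9)) "boundary" else "ok"

  # observed information on the logit scale -> Wald SEs/CIs
  H <- tryCatch(stats::optimHess(theta, occ_nll_logit,
                                 histories = histories, by_night = n_p > 1),
                error = function(e) NULL)
  se_logit <- rep(NA_real_, K)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      se_logit[d > 0] <- sqrt(d[d > 0])
    }
  }
  ci_logit <- cbind(theta - 1.96 * se_logit, theta + 1.96 * se_logit)
  prob <- plogis(theta)
  se_prob <- se_logit * prob * (1 - prob)  # delta method

  fit <- list(psi = psi_hat, p = p_hat,
              psi_se = se_prob[1], p_se = se_prob[-1],
              psi_ci = plogis(ci_logit[1, ]),
              p_ci = matrix(plogis(ci_logit[-1, , drop = FALSE]),
                            ncol = 2),
              logLik = -best$value, K = K, n_sites = nrow(histories),
              detection = detection, T_max = T_max,
              naive_occupancy = naive_psi, convergence = conv)
  class(fit) <- "occupancy_fit"
  fit
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("Occupancy model [psi(.) p(",
      if (x$detection == "constant") "." else "night", ")]\n", sep = "")
  cat(sprintf("  sites: %d  nights: %d  K: %d  logLik: %.3f  [%s]\n",
              x$n_sites, x$T_max, x$K, x$logLik, x$convergence))
  cat(sprintf("  psi = %.3f (SE %.3f)  naive = %.3f\n", x$psi, x$psi_se,
              x$naive_occupancy))
  cat("  p   =", paste(sprintf("%.3f", x$p), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.occupancy_fit <- function(object, ...) {
  structure(object$logLik, df = object$K, class = "logLik")
}

#' Cumulative detection probability over survey nights
#'
#' `P_n = 1 - prod_{i<=n} (1 - p_i)`: the probability of at least one
#' detection within the first n nights, given occupancy. Confidence
#' limits, when nightly interval endpoints are supplied, propagate the
#' endpoints through the same product.
#'
#' @param p nightly detection probabilities (vector).
#' @param lower,upper optional per-night CI endpoints for p.
#' @return Data frame of class `detection_curve` with columns `night`,
#'   `P` and (if endpoints given) `lower`, `upper`.
#' @export
cumulative_detection <- function(p, lower = NULL, upper = NULL) {
  if (length(p) == 0) stop("p is empty")
  if (any(p < 0 | p > 1)) stop("p outside [0,1]")
  out <- data.frame(night = seq_along(p), P = 1 - cumprod(1 - p))
  if (!is.null(lower)) out$lower <- 1 - cumprod(1 - lower)
  if (!is.null(upper)) out$upper <- 1 - cumprod(1 - upper)
  class(out) <- c("detection_curve", "data.frame")
  out
}

#' Survey nights needed for confident absence
#'
#' Smallest n with cumulative detection `P_n >= level`: after that many
#' undetected nights, absence can be declared with the stated confidence.
#' For a scalar p this is `ceiling(log(1 - level) / log(1 - p))`; for a
#' night-varying vector the nights are consumed in order and the result
#' may be unreachable within the vector's length.
#'
#' @param p scalar or per-night detection probability.
#' @param level required confidence in (0,1); default 0.95.
#' @return List with `nights` (integer, NA if not reached), `reached`
#'   (logical) and `achieved` (cumulative P at `nights`, or at the end of
#'   the vector when not reached).
#' @export
nights_to_confidence <- function(p, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  if (any(p < 0 | p > 1)) stop("p outside [0,1]")
  if (all(p == 0)) {
    return(list(nights = NA_integer_, reached = FALSE, achieved = 0))
  }
  if (length(p) == 1) {
    if (p == 1) return(list(nights = 1L, reached = TRUE, achieved = 1))
    n <- as.integer(ceiling(log(1 - level) / log(1 - p)))
    return(list(nights = n, reached = TRUE,
                achieved = 1 - (1 - p)^n))
  }
  P <- 1 - cumprod(1 - p)
  hit <- which(P >= level)
  if (length(hit)) {
    list(nights = as.integer(hit[1]), reached = TRUE, achieved = P[hit[1]])
  } else {
    list(nights = NA_integer_, reached = FALSE, achieved = P[length(P)])
  }
}

#' Compare detection structures for one species
#'
#' Builds the information-criterion table for a set of occupancy fits to
#' the same detection histories (e.g. constant vs night-varying
#' detection).
#'
#' @param fits list of `occupancy_fit` objects on the same data.
#' @param n effective sample size for AICc (default: number of sites).
#' @param criterion `"aic"` or `"aicc"` for ranking.
#' @return An `ic_table` data frame; see [ic_table()].
#' @export
compare_detection_models <- function(fits, n = NULL,
                                     criterion = c("aic", "aicc")) {
  criterion <- match.arg(criterion)
  ns <- vapply(fits, function(f) f$n_sites, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("fits have mismatched n_sites; not comparable")
  }
  if (is.null(n)) n <- ns[1]
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) {
      if (f$detection == "constant") "psi(.)p(.)" else "psi(.)p(night)"
    }, character(1))
  }
  ic_table(fits, n = n, criterion = criterion)
}
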