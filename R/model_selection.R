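#' @name model_selection
#' @title Negative-binomial GLMs, information criteria and model
#'   averaging
#' @description Activity counts (total 15-min events per site, with the
#'   log of nights observed as offset) are overdispersed, so candidate
#'   models are log-link negative-binomial GLMs. Candidates are compared
#'   with AIC/AICc and Akaike weights; where no single model dominates,
#'   coefficients are model-averaged over the full set with shrinkage and
#'   Burnham-Anderson unconditional standard errors.
NULL

#' Define a candidate model
#'
#' @param name label used in tables, e.g. `"C_gt1m+BD+C_gt1m*BD"`.
#' @param terms main-effect covariate names (empty = intercept-only).
#' @param interactions list of length-2 character vectors; each
#'   interaction's main effects must be in `terms` (hierarchical models
#'   only).
#' @return A `model_spec` list.
#' @export
model_spec <- function(name, terms = character(), interactions = list()) {
  for (ia in interactions) {
    if (length(ia) != 2 || !all(ia %in% terms)) {
      stop("interaction in '", name,
           "' must pair two covariates present as main effects")
    }
  }
  structure(list(name = name, terms = terms, interactions = interactions),
            class = "model_spec")
}

spec_formula <- function(spec, response = "events_total",
                         offset = "nights_observed") {
  rhs <- c(spec$terms,
           vapply(spec$interactions, paste, character(1), collapse = ":"))
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + "),
                          "+ offset(log(", offset, "))"))
}

#' A-priori candidate model sets for each rodent
#'
#' The candidate set represents the working hypotheses for what drives
#' rodent activity: upper-storey structure (`C_gt1m`), near-ground
#' structure (`C10_40`), floristic composition (`Poa+Tetra+Rhag`),
#' seabird burrow density (`BD`, split as `Atden`/`Emden`), their
#' interactions, and a constant baseline. The house-mouse set adds black
#' rat activity (`RR`) as a covariate for interference by the dominant
#' rodent.
#'
#' @param species `"black_rat"` or `"house_mouse"`.
#' @return List of [model_spec()] objects (12 for the rat, 13 for the
#'   mouse).
#' @export
candidate_sets <- function(species = c("black_rat", "house_mouse")) {
  species <- match.arg(species)
  base <- list(
    model_spec("C_gt1m", "C_gt1m"),
    model_spec("C_gt1m+BD", c("C_gt1m", "BD")),
    model_spec("C_gt1m+BD+C_gt1m*BD", c("C_gt1m", "BD"),
               list(c("C_gt1m", "BD"))),
    model_spec("Poa+Tetra+Rhag", c("Poa", "Tetra", "Rhag")),
    model_spec("Constant"),
    model_spec("C10_40", "C10_40"),
    model_spec("BD", "BD"),
    model_spec("Atden", "Atden"),
    model_spec("Emden", "Emden"),
    model_spec("C10_40+BD", c("C10_40", "BD")),
    model_spec("C10_40+BD+C10_40*BD", c("C10_40", "BD"),
               list(c("C10_40", "BD"))),
    model_spec("Emden+C10_40+Emden*C10_40", c("Emden", "C10_40"),
               list(c("Emden", "C10_40")))
  )
  if (species == "house_mouse") {
    base <- c(base, list(model_spec("RR", "RR")))
  }
  base
}

#' Fit one negative-binomial candidate model
#'
#' Log-link negative binomial with `log(nights observed)` as offset. The
#' coefficients are fitted by iteratively reweighted least squares at
#' fixed dispersion (via `glm` with the [MASS::negative.binomial()]
#' family) while the dispersion theta is profiled out by univariate
#' maximum likelihood over `log(theta)`; the reported fit maximizes the
#' joint likelihood. This profile scheme is robust on zero-heavy count
#' data where the classic alternating update can diverge.
#'
#' @param spec a [model_spec()].
#' @param data data frame containing the response, offset and covariate
#'   columns.
#' @param response name of the count column (non-negative integers).
#' @param offset name of the nights-observed column (> 0).
#' @param theta_range search interval for theta (dispersion); a maximum
#'   on the upper boundary means Poisson-like data (flagged, estimates
#'   still valid).
#' @param theta optional fixed dispersion: skips profiling and fits the
#'   coefficients at this theta (useful for examining the Poisson limit
#'   with a very large value). K still counts the dispersion.
#' @return An `nb_fit`: spec, coefficients with SEs, `theta`, `logLik`,
#'   `K` (coefficients + dispersion), `n`, convergence flag, and the
#'   underlying glm object.
#' @export
fit_nb_glm <- function(spec, data, response = "events_total",
                       offset = "nights_observed",
                       theta_range = c(1e-3, 1e6), theta = NULL) {
  y <- data[[response]]
  if (is.null(y)) stop("response column '", response, "' not found")
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative integer counts")
  }
  need <- unique(unlist(c(spec$terms, spec$interactions)))
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("covariate(s) missing from data: ", paste(miss, collapse = ", "))
  }
  f <- spec_formula(spec, response, offset)

  glm_at_theta <- function(th) {
    suppressWarnings(glm(f, family = MASS::negative.binomial(th),
                         data = data,
                         control = stats::glm.control(maxit = 100)))
  }
  profile_ll <- function(log_theta) {
    th <- exp(log_theta)
    # IRLS can blow up at extreme dispersion on zero-heavy data; treat
    # that region as likelihood floor so the search stays away from it
    g <- tryCatch(glm_at_theta(th), error = function(e) NULL)
    if (is.null(g)) return(-1e12)
    sum(stats::dnbinom(y, size = th, mu = stats::fitted(g), log = TRUE))
  }
  if (is.null(theta)) {
    opt <- stats::optimize(profile_ll, log(theta_range), maximum = TRUE,
                           tol = 1e-8)
    theta_hat <- exp(opt$maximum)
    ll_hat <- opt$objective
    at_boundary <- opt$maximum > log(theta_range[2]) - 0.01 ||
      opt$maximum < log(theta_range[1]) + 0.01
  } else {
    theta_hat <- theta
    ll_hat <- profile_ll(log(theta))
    at_boundary <- FALSE
  }
  fit <- glm_at_theta(theta_hat)

  cf <- coef(fit)
  # dispersion is profiled at its MLE, so fix the family dispersion at 1
  # (as glm.nb does) rather than using the moment estimate
  se <- sqrt(diag(suppressWarnings(vcov(fit, dispersion = 1))))
  out <- list(spec = spec, name = spec$name,
              coefficients = cf, se = se,
              theta = theta_hat,
              logLik = ll_hat,
              K = length(cf) + 1L, n = length(y),
              converged = fit$converged && !at_boundary,
              fit = fit)
  class(out) <- "nb_fit"
  out
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("NB GLM:", x$name, sprintf(" (theta = %.3g, logLik = %.3f, K = %d)\n",
                                 x$theta, x$logLik, x$K))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Akaike information criterion
#'
#' `AIC = -2 logLik + 2K`.
#'
#' @param logLik maximized log-likelihood.
#' @param K number of estimated parameters (including any dispersion).
#' @return Numeric.
#' @export
aic <- function(logLik, K) -2 * logLik + 2 * K

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2K(K+1)/(n-K-1)`.
#'
#' @inheritParams aic
#' @param n effective sample size; must exceed `K + 1`.
#' @return Numeric.
#' @export
aicc <- function(logLik, K, n) {
  if (any(n <= K + 1)) stop("aicc requires n > K + 1")
  aic(logLik, K) + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from criterion differences
#'
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)`; the vector is rebased
#' to `min(delta) = 0` first, so weights are invariant to a constant
#' shift.
#'
#' @param delta vector of AIC(c) differences.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(delta) {
  if (length(delta) == 0) stop("empty delta vector")
  delta <- delta - min(delta)
  w <- exp(-delta / 2)
  w / sum(w)
}

fit_info <- function(fit) {
  if (inherits(fit, "nb_fit")) {
    list(name = fit$name, logLik = fit$logLik, K = fit$K)
  } else if (inherits(fit, "occupancy_fit")) {
    nm <- if (fit$detection == "constant") "psi(.)p(.)" else
      "psi(.)p(night)"
    list(name = nm, logLik = fit$logLik, K = fit$K)
  } else {
    stop("unsupported fit class: ", paste(class(fit), collapse = "/"))
  }
}

#' Information-criterion comparison table
#'
#' @param fits named (or self-naming) list of `nb_fit` / `occupancy_fit`
#'   objects on the same data.
#' @param n effective sample size for AICc (number of sites).
#' @param criterion which criterion drives delta/weights/sorting:
#'   `"aicc"` (default) or `"aic"`. Both columns are always reported.
#' @return Data frame of class `ic_table`, sorted ascending by the chosen
#'   criterion, with columns `model`, `K`, `logLik`, `minus2LL`, `AIC`,
#'   `AICc`, `delta`, `weight`.
#' @export
ic_table <- function(fits, n, criterion = c("aicc", "aic")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0) stop("no fits supplied")
  info <- lapply(fits, fit_info)
  nm <- if (!is.null(names(fits)) && all(nzchar(names(fits))))
    names(fits) else vapply(info, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate model names in fit list")
  ll <- vapply(info, `[[`, numeric(1), "logLik")
  K <- vapply(info, `[[`, numeric(1), "K")
  tab <- data.frame(model = nm, K = K, logLik = ll, minus2LL = -2 * ll,
                    AIC = aic(ll, K), AICc = aicc(ll, K, n),
                    stringsAsFactors = FALSE)
  crit <- if (criterion == "aicc") tab$AICc else tab$AIC
  tab$delta <- crit - min(crit)
  tab$weight <- akaike_weights(tab$delta)
  tab <- tab[order(tab$delta), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "criterion") <- criterion
  attr(tab, "n") <- n
  class(tab) <- c("ic_table", "data.frame")
  tab
}

#' Model-averaged coefficients
#'
#' Full-set averaging with shrinkage: a covariate's coefficient is taken
#' as 0 in models that exclude it, so the average is
#' `beta_bar = sum_i w_i beta_i` over the whole candidate set. The
#' unconditional standard error follows Burnham & Anderson:
#' `SE = sum_i w_i * sqrt(SE_i^2 + (beta_i - beta_bar)^2)` (again with
#' `beta_i = 0`, `SE_i = 0` for excluding models). Relative variable
#' importance is the summed weight of the models containing the term.
#' Conditional averaging (over containing models only) is available via
#' `method = "conditional"`.
#'
#' @param table [ic_table()] for the candidate set.
#' @param fits the `nb_fit` list the table was built from.
#' @param method `"full"` (default) or `"conditional"`.
#' @param conf_level confidence level for the Wald interval.
#' @return Data frame (term, estimate, se, lower, upper, importance),
#'   intercept first.
#' @export
model_average <- function(table, fits, method = c("full", "conditional"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  nm <- vapply(fits, function(f) f$name, character(1))
  w <- table$weight[match(nm, table$model)]
  if (any(is.na(w))) stop("fit list and ic_table do not match")
  terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(terms, function(tm) {
    beta <- vapply(fits, function(f) {
      if (tm %in% names(f$coefficients)) f$coefficients[[tm]] else 0
    }, numeric(1))
    se <- vapply(fits, function(f) {
      if (tm %in% names(f$coefficients)) f$se[[tm]] else 0
    }, numeric(1))
    has <- vapply(fits, function(f) tm %in% names(f$coefficients),
                  logical(1))
    importance <- sum(w[has])
    if (method == "conditional") {
      wc <- w[has] / sum(w[has])
      est <- sum(wc * beta[has])
      use <- sum(wc * sqrt(se[has]^2 + (beta[has] - est)^2))
    } else {
      est <- sum(w * beta)
      use <- sum(w * sqrt(se^2 + (beta - est)^2))
    }
    data.frame(term = tm, estimate = est, se = use,
               lower = est - z * use, upper = est + z * use,
               importance = importance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$term != "(Intercept)"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}

#' Fit a whole candidate set and summarise it
#'
#' Convenience wrapper: fits every model in a candidate set, builds the
#' IC table and (when the top model's weight falls below
#' `average_below`, i.e. there is model-selection uncertainty)
#' model-averaged coefficients.
#'
#' @param specs list of [model_spec()] (e.g. [candidate_sets()]).
#' @param data per-site data frame with response, offset and covariates.
#' @param criterion `"aicc"` (default) or `"aic"`.
#' @param average_below top-weight threshold that triggers averaging
#'   (default 0.9; set to 1 to always average, 0 never).
#' @inheritParams fit_nb_glm
#' @return List with `fits`, `table` and `averaged` (NULL when the top
#'   model is dominant).
#' @export
select_models <- function(specs, data, response = "events_total",
                          offset = "nights_observed",
                          criterion = c("aicc", "aic"),
                          average_below = 0.9) {
  criterion <- match.arg(criterion)
  fits <- lapply(specs, fit_nb_glm, data = data, response = response,
                 offset = offset)
  names(fits) <- vapply(fits, function(f) f$name, character(1))
  tab <- ic_table(fits, n = nrow(data), criterion = criterion)
  averaged <- NULL
  if (tab$weight[1] < average_below) {
    averaged <- model_average(tab, fits)
  }
  list(fits = fits, table = tab, averaged = averaged)
}

#' @export
print.ic_table <- function(x, digits = 3, ...) {
  need <- c("model", "K", "logLik", "minus2LL", "AIC", "AICc", "delta",
            "weight")
  if (!all(need %in% names(x))) {  # column subset: plain display
    print(as.data.frame(x), row.names = FALSE)
    return(invisible(x))
  }
  cat("Model selection (", toupper(attr(x, "criterion")), ", n = ",
      attr(x, "n"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$logLik <- round(df$logLik, digits)
  df$minus2LL <- round(df$minus2LL, digits)
  df$AIC <- round(df$AIC, digits)
  df$AICc <- round(df$AICc, digits)
  df$delta <- round(df$delta, digits)
  df$weight <- round(df$weight, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
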