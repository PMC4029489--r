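#' Kaplan-Meier curve for one arm and endpoint
#'
#' Product-limit estimate of the survival function, honouring censoring
#' flags, used as the reference curve when judging which parametric family
#' best fits the observed data.
#'
#' @param ipd Pseudo-IPD data frame (see [generate_ipd()]).
#' @param arm Arm label to subset on.
#' @param endpoint One of `"OS"`, `"AML"`, `"CESSATION"`.
#' @return An object of class `km_curve`: a list with `time` (ordered event
#'   times), `surv` (product-limit estimates), `n_risk`, `n_event`,
#'   `n`, `arm`, `endpoint`. If no events are observed at all the curve is
#'   constant at 1 and a warning is signalled.
#' @export
fit_km <- function(ipd, arm, endpoint = c("OS", "AML", "CESSATION")) {
  endpoint <- match.arg(endpoint)
  validate_ipd(ipd)
  sub <- ipd[ipd$arm == arm & ipd$endpoint == endpoint, ]
  if (nrow(sub) == 0) {
    stop("no records for arm '", arm, "', endpoint '", endpoint, "'",
         call. = FALSE)
  }
  if (sum(sub$event) == 0) {
    warning("no events for arm '", arm, "', endpoint '", endpoint,
            "': survival curve is constant at 1", call. = FALSE)
  }
  sf <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = sub)
  structure(
    list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
         n_event = sf$n.event, n = nrow(sub), arm = arm, endpoint = endpoint),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Piecewise-constant (right-continuous) interpolation, 1 before the first
#' event time.
#'
#' @param km A `km_curve`.
#' @param t_days Times in days.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(km, t_days) {
  stopifnot(inherits(km, "km_curve"))
  if (length(km$time) == 0) return(rep(1, length(t_days)))
  idx <- findInterval(t_days, km$time)
  c(1, km$surv)[idx + 1]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: arm %s, endpoint %s (n = %d, events = %d)\n",
              x$arm, x$endpoint, x$n, sum(x$n_event)))
  invisible(x)
}

flexsurv_dist <- function(family) {
  switch(family, exponential = "exp", weibull = "weibull",
         lognormal = "lnorm", loglogistic = "llogis")
}

#' Fit a parametric survival family to right-censored times
#'
#' Maximum-likelihood fit of one of the four candidate families to the times
#' of one arm and endpoint, with the covariance of the estimation-scale
#' coefficients taken from the observed information. The covariance is kept
#' with the model because the probabilistic sensitivity analysis samples
#' coefficients from their joint asymptotic normal distribution.
#'
#' @inheritParams fit_km
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @return A [surv_par_model()].
#' @details Requires at least two observed events; fewer raise an
#'   insufficient-data error. Optimiser failure is rethrown as a fit-failure
#'   error carrying the underlying diagnostic message.
#' @export
fit_parametric <- function(ipd, arm, endpoint = c("OS", "AML", "CESSATION"),
                           family = c("exponential", "weibull", "lognormal",
                                      "loglogistic")) {
  endpoint <- match.arg(endpoint)
  family <- match.arg(family)
  validate_ipd(ipd)
  sub <- ipd[ipd$arm == arm & ipd$endpoint == endpoint, ]
  n_ev <- sum(sub$event)
  if (n_ev < 2) {
    stop("insufficient data: ", n_ev, " observed event(s) for arm '", arm,
         "', endpoint '", endpoint, "' (need >= 2)", call. = FALSE)
  }
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time_days, event) ~ 1, data = sub,
                          dist = flexsurv_dist(family)),
    error = function(e) {
      stop("parametric fit failed for family '", family, "', arm '", arm,
           "', endpoint '", endpoint, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  cf <- fit$res.t[, "est"]
  names(cf) <- surv_coef_names(family)
  vc <- as.matrix(fit$cov)
  dimnames(vc) <- list(names(cf), names(cf))
  surv_par_model(family, cf, vc, loglik = fit$loglik,
                 n_events = n_ev, n_censored = nrow(sub) - n_ev)
}

#' Fit all candidate families and keep every model
#'
#' @inheritParams fit_parametric
#' @param families Character vector of families to try.
#' @return Named list of [surv_par_model()] objects (families that fail to
#'   converge are dropped with a warning).
#' @export
fit_all_families <- function(ipd, arm, endpoint,
                             families = surv_families()) {
  fits <- list()
  for (f in families) {
    m <- tryCatch(fit_parametric(ipd, arm, endpoint, f),
                  error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) fits[[f]] <- m
  }
  fits
}

#' Select the best-fitting parametric family
#'
#' Chooses, among candidate models fitted to the same data, the one with the
#' smallest information criterion. Ties are broken by the canonical family
#' order (exponential, Weibull, log-normal, log-logistic), i.e. the most
#' parsimonious family listed first.
#'
#' @param models Non-empty list of [surv_par_model()] objects fitted to the
#'   same data.
#' @param criterion `"AIC"` (default) or `"BIC"`. BIC needs event and
#'   censoring counts in the models.
#' @return The selected [surv_par_model()].
#' @export
select_family <- function(models, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (length(models) == 0) stop("no candidate models supplied", call. = FALSE)
  ok <- vapply(models, inherits, logical(1), "surv_par_model")
  if (!all(ok)) stop("all candidates must be 'surv_par_model' objects", call. = FALSE)
  score <- vapply(models, function(m) {
    if (criterion == "AIC") return(aic(m))
    n <- m$n_events + m$n_censored
    if (!is.finite(n)) stop("BIC needs n_events and n_censored", call. = FALSE)
    length(m$coef) * log(n) - 2 * m$loglik
  }, numeric(1))
  fam <- vapply(models, function(m) m$family, character(1))
  ord <- order(score, match(fam, surv_families()))
  models[[ord[1]]]
}

#' Per-cycle competing-risk exit probabilities from the MDS state
#'
#' Converts the fitted overall-survival and time-to-AML curves into the
#' cycle's conditional probabilities of dying and of progressing to AML.
#' Each endpoint's raw conditional exit probability over the cycle
#' `[t0, t1) = [cycle * cycle_days, (cycle + 1) * cycle_days)` is
#' `q = 1 - S(t1)/S(t0)`. The two risks are combined assuming independent
#' cause-specific hazards: the total exit probability is
#' `1 - (1 - q_death)(1 - q_aml)`, split between the causes in proportion to
#' the cause-specific cumulative-hazard increments over the cycle.
#'
#' @param os_model,aml_model [surv_par_model()] objects for overall survival
#'   and time to AML.
#' @param cycle_index Cycle number, 0-based (`>= 0`).
#' @param cycle_days Cycle length in days (default 35, five weeks).
#' @return A list with `p_death`, `p_aml` (both in `[0, 1]`, summing to at
#'   most 1) and `absorbed` (`TRUE` when the OS curve has already reached 0
#'   at the cycle start, in which case `p_death = 1`, `p_aml = 0`).
#' @export
per_cycle_transition <- function(os_model, aml_model, cycle_index,
                                 cycle_days = 35) {
  stopifnot(inherits(os_model, "surv_par_model"),
            inherits(aml_model, "surv_par_model"))
  if (cycle_index < 0) stop("'cycle_index' must be >= 0", call. = FALSE)
  if (cycle_days <= 0) stop("'cycle_days' must be > 0", call. = FALSE)
  t0 <- cycle_index * cycle_days
  t1 <- (cycle_index + 1) * cycle_days
  s0 <- survival_at(os_model, t0)
  if (s0 <= 0) {
    return(list(p_death = 1, p_aml = 0, absorbed = TRUE))
  }
  cond_q <- function(model, t0, t1) {
    s0 <- survival_at(model, t0)
    if (s0 <= 0) return(1)
    min(max(1 - survival_at(model, t1) / s0, 0), 1)
  }
  qd <- cond_q(os_model, t0, t1)
  qa <- cond_q(aml_model, t0, t1)
  exit <- 1 - (1 - qd) * (1 - qa)
  if (exit <= 0) return(list(p_death = 0, p_aml = 0, absorbed = FALSE))
  hd <- -log1p(-min(qd, 1 - 1e-16))   # cause-specific cumulative-hazard increments
  ha <- -log1p(-min(qa, 1 - 1e-16))
  if (!is.finite(hd) || !is.finite(ha) || hd + ha == 0) {
    share_d <- if (qd >= qa) 1 else 0
  } else {
    share_d <- hd / (hd + ha)
  }
  list(p_death = exit * share_d, p_aml = exit * (1 - share_d), absorbed = FALSE)
}
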