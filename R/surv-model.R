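#' Parametric survival model for one endpoint of one arm
#'
#' Container for a fitted (or directly specified) parametric time-to-event
#' model used to extrapolate the two-year trial curves over the lifetime
#' horizon. Coefficients are stored on the *estimation scale* — the scale on
#' which maximum-likelihood asymptotics (and hence the stored covariance
#' matrix) apply: positive parameters are logged, location parameters are not.
#'
#' Supported families and their estimation-scale coefficients:
#' \describe{
#'   \item{`exponential`}{`log_rate`; S(t) = exp(-rate * t).}
#'   \item{`weibull`}{`log_shape`, `log_scale`; S(t) = exp(-(t/scale)^shape).}
#'   \item{`lognormal`}{`meanlog`, `log_sdlog`; S(t) = 1 - Phi((log t - meanlog)/sdlog).}
#'   \item{`loglogistic`}{`log_shape`, `log_scale`; S(t) = 1 / (1 + (t/scale)^shape).}
#' }
#'
#' The "logistic" family sometimes listed alongside these in health-economic
#' survival work is read here as the log-logistic distribution: a plain
#' logistic distribution admits negative event times and is not a survival
#' family.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @param coef Named numeric vector of estimation-scale coefficients (names as
#'   listed above).
#' @param vcov Coefficient covariance matrix on the estimation scale
#'   (symmetric, positive semi-definite). Defaults to a zero matrix, i.e. a
#'   model with no parameter uncertainty.
#' @param loglik Maximised log-likelihood (`NA` when the model was not fitted
#'   to data).
#' @param n_events,n_censored Event and censoring counts behind the fit.
#'
#' @return An object of class `surv_par_model`.
#' @seealso [fit_parametric()], [survival_at()], [per_cycle_transition()]
#' @export
#' @examples
#' m <- surv_par_model("lognormal", c(meanlog = log(365), log_sdlog = log(0.8)))
#' survival_at(m, 365)  # 0.5: t = exp(meanlog) is the log-normal median
surv_par_model <- function(family, coef, vcov = NULL, loglik = NA_real_,
                           n_events = NA_integer_, n_censored = NA_integer_) {
  family <- match.arg(family, surv_families())
  expected <- surv_coef_names(family)
  if (!is.numeric(coef) || length(coef) != length(expected)) {
    stop("'coef' for family '", family, "' must be numeric of length ",
         length(expected), " (", paste(expected, collapse = ", "), ")",
         call. = FALSE)
  }
  if (is.null(names(coef))) names(coef) <- expected
  if (!setequal(names(coef), expected)) {
    stop("'coef' names must be ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  coef <- coef[expected]
  if (any(!is.finite(coef))) stop("'coef' must be finite", call. = FALSE)
  if (is.null(vcov)) {
    vcov <- matrix(0, length(coef), length(coef),
                   dimnames = list(expected, expected))
  }
  vcov <- as.matrix(vcov)
  if (!isTRUE(all.equal(vcov, t(vcov), tolerance = 1e-8))) {
    stop("'vcov' must be symmetric", call. = FALSE)
  }
  ev <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("'vcov' must be positive semi-definite", call. = FALSE)
  }
  structure(
    list(family = family, coef = coef, vcov = vcov, loglik = loglik,
         n_events = as.integer(n_events), n_censored = as.integer(n_censored)),
    class = "surv_par_model"
  )
}

surv_families <- function() c("exponential", "weibull", "lognormal", "loglogistic")

surv_coef_names <- function(family) {
  switch(family,
    exponential = "log_rate",
    weibull     = c("log_shape", "log_scale"),
    lognormal   = c("meanlog", "log_sdlog"),
    loglogistic = c("log_shape", "log_scale")
  )
}

#' Natural-scale parameters of a parametric survival model
#'
#' @param model A [surv_par_model()].
#' @return Named list of parameters on the natural (positive) scale.
#' @export
natural_params <- function(model) {
  stopifnot(inherits(model, "surv_par_model"))
  cf <- model$coef
  switch(model$family,
    exponential = list(rate = exp(cf[["log_rate"]])),
    weibull     = list(shape = exp(cf[["log_shape"]]), scale = exp(cf[["log_scale"]])),
    lognormal   = list(meanlog = cf[["meanlog"]], sdlog = exp(cf[["log_sdlog"]])),
    loglogistic = list(shape = exp(cf[["log_shape"]]), scale = exp(cf[["log_scale"]]))
  )
}

#' Survival function of a fitted parametric model
#'
#' Evaluates S(t) by the family's closed form; beyond the observed follow-up
#' this *is* the extrapolation — the same closed form, with no hazard capping
#' (any horizon cap belongs to the cohort model, not the curve).
#'
#' @param model A [surv_par_model()].
#' @param t_days Vector of times in days, all `>= 0`.
#' @return Survival probabilities in `[0, 1]`, `S(0) = 1`.
#' @export
survival_at <- function(model, t_days) {
  stopifnot(inherits(model, "surv_par_model"))
  if (!is.numeric(t_days) || any(!is.finite(t_days)) || any(t_days < 0)) {
    stop("'t_days' must be finite and non-negative", call. = FALSE)
  }
  p <- natural_params(model)
  switch(model$family,
    exponential = exp(-p$rate * t_days),
    weibull     = exp(-(t_days / p$scale)^p$shape),
    lognormal   = stats::plnorm(t_days, p$meanlog, p$sdlog, lower.tail = FALSE),
    loglogistic = 1 / (1 + (t_days / p$scale)^p$shape)
  )
}

#' Cumulative hazard H(t) = -log S(t)
#' @inheritParams survival_at
#' @return Cumulative hazards (non-negative, possibly `Inf`).
#' @export
cumhaz_at <- function(model, t_days) -log(survival_at(model, t_days))

#' Akaike information criterion of a fitted model
#' @param model A [surv_par_model()] with a finite log-likelihood.
#' @return `2k - 2 logLik`.
#' @export
aic <- function(model) {
  stopifnot(inherits(model, "surv_par_model"))
  if (!is.finite(model$loglik)) stop("model has no log-likelihood", call. = FALSE)
  2 * length(model$coef) - 2 * model$loglik
}

#' @export
print.surv_par_model <- function(x, ...) {
  p <- natural_params(x)
  cat("Parametric survival model:", x$family, "\n")
  cat("  natural parameters:",
      paste(sprintf("%s = %.6g", names(p), unlist(p)), collapse = ", "), "\n")
  if (is.finite(x$loglik)) {
    cat(sprintf("  logLik = %.4f  AIC = %.4f  (events %d, censored %d)\n",
                x$loglik, aic(x), x$n_events, x$n_censored))
  }
  invisible(x)
}

#' Serialize / deserialize a parametric survival model as JSON
#'
#' @param model A [surv_par_model()].
#' @param path Optional file path; when `NULL`, the JSON string is returned.
#' @return `surv_model_to_json()`: a JSON string (invisibly, when written to
#'   file); `surv_model_from_json()`: a [surv_par_model()].
#' @export
surv_model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "surv_par_model"))
  obj <- list(
    family = model$family,
    coef = as.list(model$coef),
    vcov = model$vcov,
    loglik = model$loglik,
    n_events = model$n_events,
    n_censored = model$n_censored
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname surv_model_to_json
#' @param source A JSON string or path to a JSON file.
#' @export
surv_model_from_json <- function(source) {
  obj <- jsonlite::fromJSON(source)
  surv_par_model(
    family = obj$family,
    coef = unlist(obj$coef),
    vcov = matrix(unlist(obj$vcov), nrow = length(obj$coef)),
    loglik = if (is.null(obj$loglik)) NA_real_ else obj$loglik,
    n_events = if (is.null(obj$n_events)) NA_integer_ else obj$n_events,
    n_censored = if (is.null(obj$n_censored)) NA_integer_ else obj$n_censored
  )
}
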