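#' Moment-matched beta distribution draw for a probability-scale parameter
#'
#' Utilities, AE rates-as-probabilities and the per-cycle AML mortality have
#' no published uncertainty estimate; a plus/minus 30 percent interval around
#' the central value is assumed and read as a 95 percent interval, so
#' `sd = rel * mean / 1.96`. The beta shape parameters are matched to that
#' mean and standard deviation; when the implied interval leaves `[0, 1]`
#' the standard deviation is truncated to keep the beta feasible (a message
#' is logged).
#'
#' @param n Number of draws.
#' @param mean Central value in `(0, 1)`.
#' @param rel Relative half-width of the assumed interval (default 0.30).
#' @param z Normal quantile converting the half-width to a standard
#'   deviation (default 1.96).
#' @return `n` draws; degenerate at `mean` when `rel = 0`.
#' @export
rbeta_pm <- function(n, mean, rel = 0.30, z = 1.96) {
  if (mean <= 0 || mean >= 1) stop("'mean' must be in (0, 1)", call. = FALSE)
  if (rel == 0) return(rep(mean, n))
  s <- rel * mean / z
  s_max <- sqrt(mean * (1 - mean))
  if (s >= s_max) {
    message("beta moment matching infeasible at mean ", mean,
            ": dispersion truncated")
    s <- 0.99 * s_max
  }
  k <- mean * (1 - mean) / s^2 - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

rnorm_pm <- function(n, mean, rel = 0.30, z = 1.96, floor0 = TRUE) {
  if (rel == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, rel * abs(mean) / z)
  if (floor0) x <- pmax(x, 0)
  x
}

sample_surv_model <- function(model) {
  if (all(model$vcov == 0)) return(model)
  cf <- drop(MASS::mvrnorm(1, model$coef, model$vcov))
  names(cf) <- names(model$coef)
  surv_par_model(model$family, cf, model$vcov, loglik = model$loglik,
                 n_events = model$n_events, n_censored = model$n_censored)
}

#' Draw one coherent parameter set for the probabilistic sensitivity analysis
#'
#' One draw samples, per arm: the overall-survival, time-to-AML and
#' cessation coefficients from their joint asymptotic (multivariate normal)
#' distribution on the estimation scale using the stored fit covariance;
#' the state utilities from moment-matched beta distributions; and every
#' per-cycle cost component from a normal distribution with the plus/minus
#' 30 percent interval read as a 95 percent interval (truncated at zero).
#' The per-cycle AML mortality is drawn once, shared by all arms, from a
#' moment-matched beta. Consumes the current RNG stream, so draws are
#' deterministic given the seed.
#'
#' @param arms Named list of [arm_spec()] objects (central values).
#' @param config A [model_config()] (central AML mortality).
#' @param rel_uncertainty Relative half-width for parameters without an
#'   empirical uncertainty estimate; `0` collapses every such parameter to
#'   its central value.
#' @return A list with sampled `arms` (list of [arm_spec()]) and `config`.
#' @export
sample_parameters <- function(arms, config = model_config(),
                              rel_uncertainty = 0.30) {
  stopifnot(all(vapply(arms, inherits, logical(1), "arm_spec")))
  p_aml_death <- rbeta_pm(1, config$aml_mortality, rel_uncertainty)
  cfg <- config
  cfg$aml_mortality <- p_aml_death
  sampled <- lapply(arms, function(a) {
    draw_bundle <- function(x) {
      v <- vapply(x, function(m) if (m > 0) rnorm_pm(1, m, rel_uncertainty) else 0,
                  numeric(1))
      stats::setNames(v, names(x))
    }
    costs <- state_cost_bundle(draw_bundle(a$costs$on), draw_bundle(a$costs$off),
                               draw_bundle(a$costs$aml), arm = a$costs$arm)
    arm_spec(a$arm,
             os_model = sample_surv_model(a$os_model),
             aml_model = sample_surv_model(a$aml_model),
             cess_model = sample_surv_model(a$cess_model),
             costs = costs,
             utility_mds = rbeta_pm(1, a$utility_mds, rel_uncertainty),
             utility_aml = rbeta_pm(1, a$utility_aml, rel_uncertainty),
             single_session = a$single_session)
  })
  list(arms = sampled, config = cfg)
}

#' Run the probabilistic sensitivity analysis
#'
#' For each draw, samples one parameter set with [sample_parameters()],
#' rebuilds every arm, runs the cohort model, and records the incremental
#' discounted cost, life-years and QALYs of the intervention against each
#' comparator arm and against the patient-count-weighted pooled comparator
#' (outcome-weighting mode). Draws whose cohort run fails are flagged and
#' excluded; more than 5 percent failures aborts with an error, since that
#' indicates a mis-specified input.
#'
#' @param arms Named list of [arm_spec()] objects including the intervention.
#' @param config A [model_config()].
#' @param n_draws Number of parameter draws (the reference analysis uses
#'   50,000; tests use far fewer).
#' @param intervention Name of the intervention arm in `arms`.
#' @param comparators Names of the comparator arms.
#' @param weights [weight_set()] used for the pooled comparator (set to
#'   `NULL` to skip pooling).
#' @param rel_uncertainty Passed to [sample_parameters()].
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return An object of class `psa_result`: list with `draws` (data frame:
#'   `draw`, `comparator`, `delta_cost`, `delta_ly`, `delta_qaly`),
#'   `n_draws`, `n_failed`, `intervention`, `comparators`, `seed`.
#' @export
run_psa <- function(arms, config = model_config(), n_draws = 1000,
                    intervention = "AZA",
                    comparators = setdiff(names(arms), intervention),
                    weights = weight_set(), rel_uncertainty = 0.30,
                    seed = NULL) {
  if (n_draws < 1) stop("'n_draws' must be >= 1", call. = FALSE)
  if (!intervention %in% names(arms)) {
    stop("intervention arm '", intervention, "' not in 'arms'", call. = FALSE)
  }
  miss <- setdiff(comparators, names(arms))
  if (length(miss)) stop("comparator arm(s) not in 'arms': ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(weights)) {
    miss <- setdiff(names(weights$weights), comparators)
    if (length(miss)) stop("weight(s) without comparator arm: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- c(comparators, if (!is.null(weights)) "CCR")
  rows <- vector("list", n_draws)
  n_failed <- 0L
  for (d in seq_len(n_draws)) {
    res <- tryCatch({
      par <- sample_parameters(arms, config, rel_uncertainty)
      runs <- lapply(par$arms[c(intervention, comparators)], function(a) {
        withCallingHandlers(
          accumulate(run_cohort(a, par$config)),
          warning = function(w) invokeRestart("muffleWarning"))
      })
      int <- runs[[intervention]]
      per_comp <- lapply(comparators, function(cm) incremental(int, runs[[cm]]))
      names(per_comp) <- comparators
      if (!is.null(weights)) {
        pooled <- weighted_comparator(int, runs[comparators], weights,
                                      mode = "weight_outcomes")
        per_comp$CCR <- pooled$comparison
      }
      data.frame(
        draw = d, comparator = labels,
        delta_cost = vapply(per_comp[labels], `[[`, numeric(1), "delta_cost"),
        delta_ly = vapply(per_comp[labels], `[[`, numeric(1), "delta_ly"),
        delta_qaly = vapply(per_comp[labels], `[[`, numeric(1), "delta_qaly"),
        row.names = NULL
      )
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else rows[[d]] <- res
  }
  if (n_failed > 0.05 * n_draws) {
    stop(n_failed, " of ", n_draws, " draws failed (> 5%): ",
         "check the model specification", call. = FALSE)
  }
  structure(
    list(draws = do.call(rbind, rows), n_draws = n_draws, n_failed = n_failed,
         intervention = intervention, comparators = comparators, seed = seed),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (%d failed), %s vs %s\n", x$n_draws, x$n_failed,
              x$intervention, paste(x$comparators, collapse = "/")))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability of cost-effectiveness
#' is the fraction of PSA draws with positive net monetary benefit,
#' `wtp * delta_QALY - delta_cost > 0`.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Strictly increasing, non-empty vector of
#'   willingness-to-pay values (EUR per QALY).
#' @param comparator Which recorded comparator to use (default `"CCR"` when
#'   present, else the first).
#' @return An object of class `ceac`: data frame with columns `wtp` and
#'   `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 150000, by = 1000),
                 comparator = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0) stop("'wtp_grid' must be non-empty", call. = FALSE)
  if (any(diff(wtp_grid) <= 0)) {
    stop("'wtp_grid' must be strictly increasing", call. = FALSE)
  }
  if (is.null(psa$draws) || nrow(psa$draws) == 0) {
    stop("PSA has no successful draws", call. = FALSE)
  }
  if (is.null(comparator)) {
    comparator <- if ("CCR" %in% psa$draws$comparator) "CCR" else
      psa$draws$comparator[1]
  }
  sub <- psa$draws[psa$draws$comparator == comparator, ]
  if (nrow(sub) == 0) stop("no draws recorded for comparator '", comparator,
                           "'", call. = FALSE)
  prob <- vapply(wtp_grid, function(w) {
    mean(w * sub$delta_qaly - sub$delta_cost > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_cost_effective = prob),
            comparator = comparator, class = c("ceac", "data.frame"))
}

#' Plot a cost-effectiveness acceptability curve
#' @param x A `ceac`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$prob_cost_effective, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (EUR/QALY)",
                 ylab = "Probability cost-effective",
                 main = paste("CEAC vs", attr(x, "comparator")), ...)
  invisible(x)
}

#' Cost-effectiveness plane coordinates of the PSA draws
#'
#' @param psa A `psa_result`.
#' @param comparator Recorded comparator label.
#' @return Data frame with `delta_qaly`, `delta_cost` per successful draw.
#' @export
ce_plane <- function(psa, comparator = "CCR") {
  stopifnot(inherits(psa, "psa_result"))
  sub <- psa$draws[psa$draws$comparator == comparator, ]
  if (nrow(sub) == 0) stop("no draws recorded for comparator '", comparator,
                           "'", call. = FALSE)
  sub[c("delta_qaly", "delta_cost")]
}
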