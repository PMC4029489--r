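#' Cohort model configuration
#'
#' Global settings of the lifetime Markov cohort model: the five-week cycle,
#' the common annual discount rate for costs and effects, the constant
#' per-cycle AML mortality shared by all arms, and the horizon rule.
#' "End-of-life" is operationalised as running until the alive fraction
#' drops below `epsilon` (default 1e-6) or a hard cap of `max_cycles`
#' (default 520 cycles, about 50 years) is reached.
#'
#' @param cycle_days Cycle length in days (default 35: five weeks).
#' @param discount_rate Annual discount rate applied to both costs and
#'   effects (default 0.03).
#' @param aml_mortality Constant per-cycle probability of death in the AML
#'   state (default 0.135), identical for all treatment arms.
#' @param epsilon Alive-fraction threshold ending the simulation.
#' @param max_cycles Hard cap on the number of cycles.
#' @param half_cycle_correction Accrue costs and effects on the mean of
#'   cycle-start and cycle-end occupancy instead of cycle-start occupancy.
#'   Off by default: the per-cycle cost tables and lifetime totals are
#'   consistent with cycle-start accrual.
#' @param days_per_year Days per year used to convert cycles to years.
#' @return An object of class `model_config`.
#' @export
model_config <- function(cycle_days = 35, discount_rate = 0.03,
                         aml_mortality = 0.135, epsilon = 1e-6,
                         max_cycles = 520L, half_cycle_correction = FALSE,
                         days_per_year = 365.25) {
  if (cycle_days <= 0) stop("'cycle_days' must be > 0", call. = FALSE)
  if (discount_rate < 0 || discount_rate >= 1) {
    stop("'discount_rate' must be in [0, 1)", call. = FALSE)
  }
  if (aml_mortality < 0 || aml_mortality > 1) {
    stop("'aml_mortality' must be in [0, 1]", call. = FALSE)
  }
  if (max_cycles < 1) stop("'max_cycles' must be >= 1", call. = FALSE)
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  structure(
    list(cycle_days = cycle_days, discount_rate = discount_rate,
         aml_mortality = aml_mortality, epsilon = epsilon,
         max_cycles = as.integer(max_cycles),
         half_cycle_correction = isTRUE(half_cycle_correction),
         days_per_year = days_per_year),
    class = "model_config"
  )
}

#' Arm specification for the cohort model
#'
#' Bundles everything the cohort simulation needs for one treatment arm: the
#' three fitted time-to-event models (overall survival, time to AML,
#' treatment cessation), the per-cycle state cost bundle, and the state
#' utilities. Baseline MDS utility is 0.67 for azacitidine, BSC and LDC and
#' 0.66 for SDC; the AML utility is 0.52 for every arm.
#'
#' @param arm Arm label.
#' @param os_model,aml_model,cess_model [surv_par_model()] objects for
#'   overall survival, time to AML, and time on first-line treatment.
#' @param costs A [state_cost_bundle()].
#' @param utility_mds,utility_aml State utilities in `[0, 1]`.
#' @param single_session When `TRUE` (standard-dose chemotherapy), only one
#'   treatment session is costed: the on-treatment fraction is forced to 0
#'   from the second cycle onwards.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(arm, os_model, aml_model, cess_model, costs,
                     utility_mds = 0.67, utility_aml = 0.52,
                     single_session = FALSE) {
  for (m in list(os_model, aml_model, cess_model)) {
    if (!inherits(m, "surv_par_model")) {
      stop("os_model, aml_model and cess_model must be 'surv_par_model' objects",
           call. = FALSE)
    }
  }
  stopifnot(inherits(costs, "state_cost_bundle"))
  for (u in c(utility_mds, utility_aml)) {
    if (!is.numeric(u) || u < 0 || u > 1) {
      stop("utilities must be in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(arm = arm, os_model = os_model, aml_model = aml_model,
         cess_model = cess_model, costs = costs,
         utility_mds = utility_mds, utility_aml = utility_aml,
         single_session = isTRUE(single_session)),
    class = "arm_spec"
  )
}

#' Discount factor at the start of a cycle
#'
#' `(1 + r)^(-t_years)` with `t_years = cycle_index * cycle_days /
#' days_per_year`, evaluated at cycle start.
#'
#' @param cycle_index 0-based cycle number (vectorised).
#' @param config A [model_config()].
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, config = model_config()) {
  if (any(cycle_index < 0)) stop("'cycle_index' must be >= 0", call. = FALSE)
  t_years <- cycle_index * config$cycle_days / config$days_per_year
  (1 + config$discount_rate)^(-t_years)
}

#' One Markov transition of the cohort state vector
#'
#' Moves the occupancy vector `(mds, aml, dead)` through one cycle: MDS
#' occupants die with probability `p_death_mds` or progress to AML with
#' probability `p_aml`; AML occupants die with probability `p_death_aml`.
#' Death is absorbing and mass is conserved exactly.
#'
#' @param state Numeric `c(mds, aml, dead)` occupancy fractions.
#' @param p_death_mds,p_aml,p_death_aml Per-cycle probabilities in `[0, 1]`
#'   with `p_death_mds + p_aml <= 1`.
#' @return The next state vector.
#' @export
markov_step <- function(state, p_death_mds, p_aml, p_death_aml) {
  if (length(state) != 3 || any(state < 0)) {
    stop("'state' must be a non-negative vector (mds, aml, dead)", call. = FALSE)
  }
  pr <- c(p_death_mds, p_aml, p_death_aml)
  if (any(pr < 0) || any(pr > 1)) {
    stop("transition probabilities must be in [0, 1]", call. = FALSE)
  }
  if (p_death_mds + p_aml > 1 + 1e-12) {
    stop("p_death_mds + p_aml must not exceed 1", call. = FALSE)
  }
  mds <- state[1]; aml <- state[2]; dead <- state[3]
  c(mds = mds * (1 - p_death_mds - p_aml),
    aml = aml * (1 - p_death_aml) + mds * p_aml,
    dead = dead + mds * p_death_mds + aml * p_death_aml)
}

#' Run the lifetime cohort simulation for one arm
#'
#' Propagates a cohort (by default starting fully in MDS, on first-line
#' treatment) through five-week cycles until the alive fraction falls below
#' the configured epsilon or the cycle cap is reached. Each cycle:
#' \itemize{
#'   \item MDS exits come from [per_cycle_transition()] applied to the arm's
#'     OS and AML curves; AML mortality is the constant per-cycle rate.
#'   \item The fraction of MDS occupants still on treatment equals the
#'     cessation curve `S_cess(cycle * cycle_days)` (0 from cycle 1 onwards
#'     under `single_session`); it weights the on/off per-cycle costs.
#'     Patients who progressed to AML receive BSC-pattern costs only.
#'   \item Costs, life-years and QALYs accrue on cycle-start occupancy
#'     (or the start/end mean with the half-cycle option) and are discounted
#'     at the cycle-start discount factor.
#' }
#'
#' @param arm An [arm_spec()].
#' @param config A [model_config()].
#' @param init_state Initial occupancy `c(mds, aml, dead)`, summing to 1.
#' @return A `cohort_trace`: a data frame with one row per cycle (`cycle`,
#'   `mds`, `aml`, `dead`, `on_frac`, `cost`, `cost_disc`, `ly_disc`,
#'   `qaly_disc`) and attributes `arm`, `truncated` (cap reached with the
#'   alive fraction still above epsilon).
#' @export
run_cohort <- function(arm, config = model_config(), init_state = c(1, 0, 0)) {
  stopifnot(inherits(arm, "arm_spec"), inherits(config, "model_config"))
  if (length(init_state) != 3 || any(init_state < 0) ||
      abs(sum(init_state) - 1) > 1e-9) {
    stop("'init_state' must be non-negative and sum to 1", call. = FALSE)
  }
  cd <- config$cycle_days
  n_max <- config$max_cycles
  dpy <- config$days_per_year

  # cycle-boundary survival evaluations, vectorised once
  t_grid <- (0:n_max) * cd
  s_os <- survival_at(arm$os_model, t_grid)
  s_aml <- survival_at(arm$aml_model, t_grid)
  on_frac_all <- survival_at(arm$cess_model, t_grid)
  if (arm$single_session && n_max >= 1) on_frac_all[-1] <- 0
  df_all <- discount_factor(0:n_max, config)

  cost_on <- arm$costs$totals[["on"]]
  cost_off <- arm$costs$totals[["off"]]
  cost_aml <- arm$costs$totals[["aml"]]

  cycles <- integer(0)
  occ <- matrix(NA_real_, n_max, 3)
  on_frac <- cost <- cost_disc <- ly_disc <- qaly_disc <- numeric(n_max)

  state <- c(init_state[1], init_state[2], init_state[3])
  n_used <- 0L
  for (k in seq_len(n_max)) {
    i <- k - 1L   # 0-based cycle index
    if (state[1] + state[2] < config$epsilon) break
    # per-cycle MDS exit probabilities over [i*cd, (i+1)*cd)
    if (s_os[k] <= 0) {
      p_death <- 1; p_aml <- 0
    } else {
      qd <- min(max(1 - s_os[k + 1] / s_os[k], 0), 1)
      qa <- if (s_aml[k] <= 0) 1 else min(max(1 - s_aml[k + 1] / s_aml[k], 0), 1)
      exit <- 1 - (1 - qd) * (1 - qa)
      if (exit <= 0) {
        p_death <- 0; p_aml <- 0
      } else {
        hd <- -log1p(-min(qd, 1 - 1e-16))
        ha <- -log1p(-min(qa, 1 - 1e-16))
        share_d <- if (!is.finite(hd) || !is.finite(ha) || hd + ha == 0) {
          if (qd >= qa) 1 else 0
        } else hd / (hd + ha)
        p_death <- exit * share_d; p_aml <- exit * (1 - share_d)
      }
    }
    nxt <- markov_step(state, p_death, p_aml, config$aml_mortality)
    w <- if (config$half_cycle_correction) (state + nxt) / 2 else state
    of <- on_frac_all[k]
    c_cycle <- w[1] * (of * cost_on + (1 - of) * cost_off) + w[2] * cost_aml
    ly <- (w[1] + w[2]) * cd / dpy
    qaly <- (w[1] * arm$utility_mds + w[2] * arm$utility_aml) * cd / dpy

    n_used <- k
    cycles[k] <- i
    occ[k, ] <- state
    on_frac[k] <- of
    cost[k] <- c_cycle
    cost_disc[k] <- c_cycle * df_all[k]
    ly_disc[k] <- ly * df_all[k]
    qaly_disc[k] <- qaly * df_all[k]
    state <- nxt
  }
  truncated <- (state[1] + state[2]) >= config$epsilon
  if (truncated) {
    warning("horizon cap (", n_max, " cycles) reached with alive fraction ",
            signif(state[1] + state[2], 3), " still above epsilon",
            call. = FALSE)
  }
  idx <- seq_len(n_used)
  trace <- data.frame(
    cycle = cycles[idx], mds = occ[idx, 1], aml = occ[idx, 2],
    dead = occ[idx, 3], on_frac = on_frac[idx], cost = cost[idx],
    cost_disc = cost_disc[idx], ly_disc = ly_disc[idx],
    qaly_disc = qaly_disc[idx]
  )
  attr(trace, "arm") <- arm$arm
  attr(trace, "truncated") <- truncated
  attr(trace, "final_state") <- state
  class(trace) <- c("cohort_trace", "data.frame")
  trace
}

#' Lifetime totals of a cohort trace
#'
#' Sums the discounted per-cycle cost, life-year and QALY increments into
#' lifetime totals for the arm.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param arm Optional label overriding the trace's arm attribute.
#' @return An [arm_result()].
#' @export
accumulate <- function(trace, arm = NULL) {
  stopifnot(inherits(trace, "cohort_trace") || is.data.frame(trace))
  label <- if (!is.null(arm)) arm else attr(trace, "arm")
  if (is.null(label)) label <- NA_character_
  if (nrow(trace) == 0) return(arm_result(label, 0, 0, 0))
  arm_result(label,
             cost = sum(trace$cost_disc),
             ly = sum(trace$ly_disc),
             qaly = sum(trace$qaly_disc))
}

#' Write a cohort trace as CSV
#' @param trace A `cohort_trace`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
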