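#' Unit costs of resources (EUR, 2012)
#'
#' Named vector of Spanish NHS unit costs used to build per-cycle state
#' costs: hospital and visit costs, routine tests, transfusions and
#' adverse-event episode costs. Defaults are the packaged table; any entry
#' can be overridden.
#'
#' @param ... Named overrides, e.g. `inpatient_day = 800`.
#' @return Named numeric vector of unit costs in EUR.
#' @export
unit_costs <- function(...) {
  tab <- utils::read.csv(mdscea_file("unit_costs.csv"), stringsAsFactors = FALSE)
  uc <- stats::setNames(tab$eur, tab$resource)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(uc))
    if (length(bad)) stop("unknown unit cost(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    uc[names(over)] <- unlist(over)
  }
  if (any(uc < 0)) stop("unit costs must be >= 0", call. = FALSE)
  uc
}

mdscea_file <- function(...) {
  p <- system.file("extdata", ..., package = "mdscea", mustWork = FALSE)
  if (identical(p, "")) stop("packaged data file not found: ",
                             file.path(...), call. = FALSE)
  p
}

#' Drug regimen: agents, doses and treatment days per cycle
#'
#' @param components Data frame with columns `agent`, `cost_per_mg` (EUR),
#'   `dose_mg_m2` and `days_per_cycle`.
#' @param bsa Body-surface area in m2 scaling the mg/m2 doses. The printed
#'   cost tables do not state the BSA; 1.70 m2 is adopted, back-calculated
#'   from the low-dose cytarabine row (48.38 / (0.0271 * 150 * 7) = 1.700).
#'   Implied BSA varies slightly (1.687-1.700) across printed rows; see the
#'   methods vignette.
#' @return An object of class `drug_regimen`.
#' @export
drug_regimen <- function(components, bsa = 1.70) {
  need <- c("agent", "cost_per_mg", "dose_mg_m2", "days_per_cycle")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("'components' missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  num <- c("cost_per_mg", "dose_mg_m2", "days_per_cycle")
  for (f in num) {
    if (any(!is.finite(components[[f]]) | components[[f]] < 0)) {
      stop("'", f, "' must be non-negative and finite", call. = FALSE)
    }
  }
  if (!is.numeric(bsa) || length(bsa) != 1 || bsa <= 0) {
    stop("'bsa' must be a single positive number", call. = FALSE)
  }
  structure(list(components = components[need], bsa = bsa),
            class = "drug_regimen")
}

#' Pharmacology cost per cycle of a drug regimen
#'
#' With `wastage_mode = "none"` the cost is the exact milligram price:
#' sum over agents of `cost_per_mg * dose_mg_m2 * bsa * days_per_cycle`.
#' With `"vial_round_up"` the per-administration dose is rounded up to whole
#' vials of the configured size before pricing, charging the unused part of
#' the last vial. The printed per-cycle costs are reproduced by exact-mg
#' arithmetic, so `"none"` is the default; the vial option is provided for
#' wastage sensitivity analyses.
#'
#' @param regimen A [drug_regimen()].
#' @param wastage_mode `"none"` or `"vial_round_up"`.
#' @param vial_size_mg Named numeric vector of vial sizes in mg per agent;
#'   required (for every agent) when `wastage_mode = "vial_round_up"`.
#' @return Cost per cycle in EUR.
#' @export
#' @examples
#' ldc <- drug_regimen(data.frame(agent = "cytarabine", cost_per_mg = 0.0271,
#'                                dose_mg_m2 = 150, days_per_cycle = 7))
#' drug_cost_per_cycle(ldc)  # 48.37, printed as 48.38
drug_cost_per_cycle <- function(regimen, wastage_mode = c("none", "vial_round_up"),
                                vial_size_mg = NULL) {
  stopifnot(inherits(regimen, "drug_regimen"))
  wastage_mode <- match.arg(wastage_mode)
  cmp <- regimen$components
  if (nrow(cmp) == 0) return(0)
  mg_per_admin <- cmp$dose_mg_m2 * regimen$bsa
  if (wastage_mode == "vial_round_up") {
    if (is.null(vial_size_mg) || is.null(names(vial_size_mg))) {
      stop("'vial_size_mg' (named, mg per vial) is required for wastage_mode = 'vial_round_up'",
           call. = FALSE)
    }
    miss <- setdiff(cmp$agent, names(vial_size_mg))
    if (length(miss)) stop("no vial size configured for agent(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    vial <- vial_size_mg[cmp$agent]
    mg_per_admin <- ceiling(mg_per_admin / vial) * vial
  }
  sum(cmp$cost_per_mg * mg_per_admin * cmp$days_per_cycle)
}

#' Per-cycle cost bundle for one treatment arm's health states
#'
#' Holds the per-cycle EUR cost components of the three costed situations:
#' MDS on first-line treatment, MDS off treatment, and AML (where every arm
#' receives best-supportive-care-pattern management). Totals are always the
#' sums of the stored components.
#'
#' @param on,off,aml Named numeric vectors of non-negative per-cycle EUR
#'   components.
#' @param arm Optional arm label.
#' @return An object of class `state_cost_bundle` with `$totals` holding the
#'   three state totals.
#' @export
state_cost_bundle <- function(on, off, aml, arm = NA_character_) {
  for (nm in c("on", "off", "aml")) {
    x <- get(nm)
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
      stop("'", nm, "' components must be non-negative and finite", call. = FALSE)
    }
  }
  structure(
    list(arm = arm, on = on, off = off, aml = aml,
         totals = c(on = sum(on), off = sum(off), aml = sum(aml))),
    class = "state_cost_bundle"
  )
}

#' @export
print.state_cost_bundle <- function(x, ...) {
  cat(sprintf("Per-cycle state costs%s (EUR): on %.2f, off %.2f, AML %.2f\n",
              if (is.na(x$arm)) "" else paste0(" [", x$arm, "]"),
              x$totals[["on"]], x$totals[["off"]], x$totals[["aml"]]))
  invisible(x)
}

#' Per-cycle cost of a health state
#'
#' @param bundle A [state_cost_bundle()].
#' @param state `"mds"` or `"aml"`.
#' @param on_treatment For the MDS state, whether the patient is on
#'   first-line treatment (ignored for AML).
#' @return Cost per cycle in EUR (sum of the state's components).
#' @export
state_cost_per_cycle <- function(bundle, state, on_treatment = TRUE) {
  stopifnot(inherits(bundle, "state_cost_bundle"))
  if (!state %in% c("mds", "aml")) {
    stop("unknown state '", state, "' (expected 'mds' or 'aml')", call. = FALSE)
  }
  if (state == "aml") return(bundle$totals[["aml"]])
  if (on_treatment) bundle$totals[["on"]] else bundle$totals[["off"]]
}

#' Adverse-event cost per model cycle from annualised rates
#'
#' Converts trial-annualised adverse-event rates to the five-week cycle and
#' prices them with the per-episode unit costs:
#' `sum(rate_per_year * cycle_days / days_per_year * unit_cost)`.
#'
#' @param annual_rates Named numeric vector of events per patient-year; names
#'   must be adverse events present in `costs`.
#' @param costs Unit-cost vector from [unit_costs()].
#' @param cycle_days,days_per_year Cycle length and year length in days.
#' @return Cost per cycle in EUR.
#' @export
ae_cost_per_cycle <- function(annual_rates, costs = unit_costs(),
                              cycle_days = 35, days_per_year = 365.25) {
  if (length(annual_rates) == 0) return(0)
  if (is.null(names(annual_rates)) || any(names(annual_rates) == "")) {
    stop("'annual_rates' must be a named vector", call. = FALSE)
  }
  if (any(annual_rates < 0)) stop("adverse-event rates must be >= 0", call. = FALSE)
  known <- intersect(names(costs),
                     c("neutropenia", "leucopenia", "febrile_neutropenia",
                       "pyrexia", "pneumonia", "sepsis"))
  bad <- setdiff(names(annual_rates), names(costs))
  if (length(bad)) {
    stop("unknown adverse event(s): ", paste(bad, collapse = ", "),
         "; known adverse events: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  sum(annual_rates * (cycle_days / days_per_year) * costs[names(annual_rates)])
}

#' Packaged cost tables
#'
#' Loads the packaged delimited-text cost tables: unit costs of resources,
#' pharmacological regimens with printed per-cycle costs, and the per-cycle
#' state cost components of the four treatment arms.
#'
#' @return A list with data frames `unit_costs`, `drug_regimens`,
#'   `state_costs`.
#' @export
mds_cost_tables <- function() {
  list(
    unit_costs = utils::read.csv(mdscea_file("unit_costs.csv"),
                                 stringsAsFactors = FALSE),
    drug_regimens = utils::read.csv(mdscea_file("drug_regimens.csv"),
                                    stringsAsFactors = FALSE),
    state_costs = utils::read.csv(mdscea_file("state_costs.csv"),
                                  stringsAsFactors = FALSE)
  )
}

#' Per-arm state cost bundles from the packaged tables
#'
#' Builds one [state_cost_bundle()] per treatment arm from the packaged
#' per-cycle component table (the carried, printed decomposition; full
#' precision is the printed cent precision).
#'
#' @param state_costs Long-format data frame with columns `arm`, `state`
#'   (`on` / `off` / `aml`), `component`, `eur`; defaults to the packaged
#'   table.
#' @return Named list of [state_cost_bundle()] objects (AZA, BSC, LDC, SDC
#'   for the packaged table).
#' @export
arm_cost_bundles <- function(state_costs = mds_cost_tables()$state_costs) {
  need <- c("arm", "state", "component", "eur")
  miss <- setdiff(need, names(state_costs))
  if (length(miss)) stop("'state_costs' missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  arms <- unique(state_costs$arm)
  out <- lapply(arms, function(a) {
    sub <- state_costs[state_costs$arm == a, ]
    pick <- function(st) {
      s <- sub[sub$state == st, ]
      stats::setNames(s$eur, s$component)
    }
    state_cost_bundle(pick("on"), pick("off"), pick("aml"), arm = a)
  })
  stats::setNames(out, arms)
}
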