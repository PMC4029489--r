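default_config_values <- function() {
  list(
    cycle_days = 35, discount_rate = 0.03, aml_mortality = 0.135,
    epsilon = 1e-6, max_cycles = 520L, half_cycle_correction = FALSE,
    days_per_year = 365.25,
    utilities = list(AZA = 0.67, BSC = 0.67, LDC = 0.67, SDC = 0.66,
                     AML = 0.52),
    weights = list(AZA = 110, BSC = 79, LDC = 38, SDC = 20),
    wtp_per_qaly = 50000,
    bsa = 1.70,
    rel_uncertainty = 0.30,
    n_psa_draws = 50000L
  )
}

#' Load (or default) the analysis configuration
#'
#' Reads a YAML or JSON configuration file, fills every unset key with the
#' reference-analysis default (35-day cycle, 3 percent discounting, AML
#' mortality 0.135 per cycle, utilities 0.67/0.66 for MDS and 0.52 for AML,
#' patient weights 110/79/38/20, willingness to pay 50,000 EUR/QALY) and
#' validates ranges. Unknown keys are rejected by name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; `NULL` (or an empty
#'   file) yields the full default configuration.
#' @return A validated named list of class `cea_config`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else if (ext == "json") {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      stop("unsupported config format '", ext, "' (use yaml or json)",
           call. = FALSE)
    }
    if (is.null(user)) user <- list()
  }
  defaults <- default_config_values()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  validate_config(cfg)
  structure(cfg, class = "cea_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop("configuration key '", key, "' ", what, call. = FALSE)
  }
  chk(cfg$cycle_days > 0, "cycle_days", "must be > 0")
  chk(cfg$discount_rate >= 0 && cfg$discount_rate < 1, "discount_rate",
      "must be in [0, 1)")
  chk(cfg$aml_mortality >= 0 && cfg$aml_mortality <= 1, "aml_mortality",
      "must be in [0, 1]")
  chk(cfg$max_cycles >= 1, "max_cycles", "must be >= 1")
  chk(cfg$epsilon >= 0, "epsilon", "must be >= 0")
  chk(all(unlist(cfg$utilities) >= 0 & unlist(cfg$utilities) <= 1),
      "utilities", "must all be in [0, 1]")
  chk(all(unlist(cfg$weights) >= 0) && sum(unlist(cfg$weights)) > 0,
      "weights", "must be non-negative, not all zero")
  chk(cfg$wtp_per_qaly >= 0, "wtp_per_qaly", "must be >= 0")
  chk(cfg$bsa > 0, "bsa", "must be > 0")
  chk(cfg$rel_uncertainty >= 0, "rel_uncertainty", "must be >= 0")
  chk(cfg$n_psa_draws >= 1, "n_psa_draws", "must be >= 1")
  invisible(cfg)
}

#' Save a configuration as YAML
#' @param config A `cea_config` from [load_config()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' As a [model_config()] for the cohort engine
#' @param config A `cea_config`.
#' @return A [model_config()].
#' @export
as_model_config <- function(config) {
  model_config(cycle_days = config$cycle_days,
               discount_rate = config$discount_rate,
               aml_mortality = config$aml_mortality,
               epsilon = config$epsilon, max_cycles = config$max_cycles,
               half_cycle_correction = config$half_cycle_correction,
               days_per_year = config$days_per_year)
}

#' Run the full simulate / fit / run / compare / PSA pipeline
#'
#' End-to-end orchestration: generate (or read) pseudo individual-patient
#' data, fit the candidate survival families per arm and endpoint (AIC
#' selection for overall survival and time to AML, Weibull for treatment
#' cessation), build the arm specifications with the packaged per-cycle cost
#' bundles, run the lifetime cohort model, compute the pairwise and
#' patient-count-weighted incremental results, run the probabilistic
#' sensitivity analysis, and write all tabular outputs plus a run manifest
#' to `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param scenario A [trial_scenario()] used to simulate the trial data
#'   (ignored when `ipd` is supplied).
#' @param ipd Optional pseudo-IPD data frame or path to an IPD CSV.
#' @param config A `cea_config` from [load_config()].
#' @param n_psa Number of PSA draws for this run (the configuration's
#'   `n_psa_draws` is the reference-analysis size; pass a smaller number for
#'   quick runs). `0` skips the PSA.
#' @param psa_seed Seed for the PSA stage.
#' @return Invisibly, a list with `results` (per-arm [arm_result()]s),
#'   `comparisons`, `weighted` (both pooling modes), `psa`, `ceac`,
#'   `manifest`, and the paths written.
#' @export
run_pipeline <- function(out_dir, scenario = default_scenario(), ipd = NULL,
                         config = load_config(), n_psa = 1000,
                         psa_seed = scenario$seed) {
  stopifnot(inherits(config, "cea_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_status <- list()
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      stage_status[[name]] <<- paste("failed:", conditionMessage(e))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    stage_status[[name]] <<- "ok"
    res
  }

  ipd <- stage("simulate-data", {
    if (is.null(ipd)) generate_ipd(scenario)
    else if (is.character(ipd)) read_ipd(ipd)
    else validate_ipd(ipd)
  })
  ipd_path <- file.path(out_dir, "ipd.csv")
  write_ipd(ipd, ipd_path)

  arms_avail <- intersect(c("AZA", "BSC", "LDC", "SDC"), unique(ipd$arm))
  mcfg <- as_model_config(config)
  bundles <- arm_cost_bundles()

  fits <- stage("fit-survival", {
    lapply(stats::setNames(arms_avail, arms_avail), function(a) {
      os <- select_family(fit_all_families(ipd, a, "OS"))
      aml <- select_family(fit_all_families(ipd, a, "AML"))
      cess <- fit_parametric(ipd, a, "CESSATION", "weibull")
      list(os = os, aml = aml, cess = cess)
    })
  })
  for (a in arms_avail) {
    surv_model_to_json(fits[[a]]$os, file.path(out_dir, paste0("fit-", a, "-OS.json")))
  }

  specs <- stage("build-arms", {
    lapply(stats::setNames(arms_avail, arms_avail), function(a) {
      arm_spec(a, fits[[a]]$os, fits[[a]]$aml, fits[[a]]$cess,
               costs = bundles[[a]],
               utility_mds = config$utilities[[a]],
               utility_aml = config$utilities$AML,
               single_session = identical(a, "SDC"))
    })
  })

  results <- stage("run-cea", {
    lapply(specs, function(sp) {
      tr <- withCallingHandlers(run_cohort(sp, mcfg),
                                warning = function(w) invokeRestart("muffleWarning"))
      write_trace(tr, file.path(out_dir, paste0("trace-", sp$arm, ".csv")))
      accumulate(tr)
    })
  })

  comparators <- setdiff(arms_avail, "AZA")
  cea_out <- stage("compare", {
    cmp <- lapply(stats::setNames(comparators, comparators), function(cm) {
      incremental(results$AZA, results[[cm]])
    })
    w <- weight_set(unlist(config$weights[comparators]),
                    intervention_weight = config$weights$AZA)
    pooled_out <- weighted_comparator(results$AZA, results[comparators], w,
                                      mode = "weight_outcomes")
    pooled_icer <- weighted_comparator(results$AZA, results[comparators], w,
                                       mode = "weight_icers")
    cmp$CCR <- pooled_out$comparison
    tab <- cea_table(cmp)
    utils::write.csv(format(tab, digits = 15), file.path(out_dir, "cea_results.csv"),
                     row.names = FALSE, quote = FALSE)
    list(comparisons = cmp, weighted_outcomes = pooled_out,
         weighted_icers = pooled_icer, table = tab)
  })

  psa_res <- ceac_res <- NULL
  if (n_psa > 0) {
    psa_res <- stage("run-psa", {
      w <- weight_set(unlist(config$weights[comparators]),
                      intervention_weight = config$weights$AZA)
      run_psa(specs, mcfg, n_draws = n_psa, intervention = "AZA",
              comparators = comparators, weights = w,
              rel_uncertainty = config$rel_uncertainty, seed = psa_seed)
    })
    ceac_res <- stage("ceac", {
      cc <- ceac(psa_res)
      utils::write.csv(format(as.data.frame(cc), digits = 15),
                       file.path(out_dir, "ceac.csv"),
                       row.names = FALSE, quote = FALSE)
      cc
    })
  }

  manifest <- stage("manifest", {
    outputs <- list.files(out_dir, full.names = TRUE)
    outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
    m <- list(
      package = "mdscea",
      version = as.character(utils::packageVersion("mdscea")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      scenario_seed = scenario$seed,
      psa_seed = psa_seed,
      n_psa = n_psa,
      config = unclass(config),
      stages = stage_status,
      output_digests = as.list(tools::md5sum(sort(outputs)))
    )
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  invisible(list(ipd = ipd, fits = fits, results = results,
                 comparisons = cea_out$comparisons,
                 weighted = list(outcomes = cea_out$weighted_outcomes,
                                 icers = cea_out$weighted_icers),
                 table = cea_out$table, psa = psa_res, ceac = ceac_res,
                 manifest = manifest, out_dir = out_dir))
}
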