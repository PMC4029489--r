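# Small constructors used across tests: parametric models with known
# parameters, flat cost bundles, and a one-arm scenario builder.

ln_model <- function(meanlog, sdlog, vcov = NULL) {
  surv_par_model("lognormal", c(meanlog = meanlog, log_sdlog = log(sdlog)),
                 vcov = vcov)
}

exp_model <- function(rate, vcov = NULL) {
  surv_par_model("exponential", c(log_rate = log(rate)), vcov = vcov)
}

wb_model <- function(shape, scale, vcov = NULL) {
  surv_par_model("weibull", c(log_shape = log(shape), log_scale = log(scale)),
                 vcov = vcov)
}

# effectively-zero hazard: rate 1e-300 keeps coefficients finite
null_model <- function() exp_model(1e-300)

flat_bundle <- function(on = 100, off = 50, aml = 80) {
  state_cost_bundle(c(total = on), c(total = off), c(total = aml))
}

one_arm_scenario <- function(n, os = c(log(365), 0.8),
                             aml = c(log(500), 0.8), cess = c(1.2, 300),
                             censor_days = 730, seed = 1L, arm = "AZA") {
  trial_scenario(
    arms = list(list(arm = arm, os_params = os, aml_params = aml,
                     cess_params = cess, n_patients = n)),
    censor_days = censor_days, seed = seed
  )
}

# a plausible fitted-scale arm for cohort-level tests
test_arm <- function(arm = "AZA", utility_mds = 0.67, single_session = FALSE) {
  arm_spec(arm,
           os_model = ln_model(log(700), 0.9),
           aml_model = ln_model(log(540), 0.9),
           cess_model = wb_model(1.3, 420),
           costs = flat_bundle(4911.24, 1627.78, 1851.86),
           utility_mds = utility_mds, utility_aml = 0.52,
           single_session = single_session)
}
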