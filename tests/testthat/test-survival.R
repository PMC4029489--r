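make_ipd <- function(time, event, arm = "AZA", endpoint = "OS") {
  data.frame(patient_id = sprintf("p%03d", seq_along(time)), arm = arm,
             endpoint = endpoint, time_days = time, event = as.integer(event),
             stringsAsFactors = FALSE)
}

test_that("fit_km reproduces the textbook product-limit estimate", {
  km <- fit_km(make_ipd(c(1, 2, 3), c(1, 1, 1)), "AZA", "OS")
  expect_equal(km$surv, c(2/3, 1/3, 0))
  expect_equal(km$time, c(1, 2, 3))
  # censoring between events changes the risk set
  km2 <- fit_km(make_ipd(c(1, 1.5, 3), c(1, 0, 1)), "AZA", "OS")
  expect_equal(km2$surv[km2$time == 3], 2/3 * 0)
  expect_equal(km_survival_at(km, c(0.5, 1, 2.5)), c(1, 2/3, 1/3))
})

test_that("fit_km warns and stays at 1 when no events are observed", {
  expect_warning(km <- fit_km(make_ipd(c(5, 6), c(0, 0)), "AZA", "OS"),
                 "no events")
  expect_true(all(km$surv == 1))
  expect_error(fit_km(make_ipd(1, 1), "NOPE", "OS"), "no records")
})

test_that("Kaplan-Meier converges to the exponential closed form", {
  set.seed(301)
  t <- rexp(10000, rate = 0.01)
  km <- fit_km(make_ipd(t, rep(1, 10000)), "AZA", "OS")
  expect_lt(max(abs(km$surv - exp(-0.01 * km$time))), 0.02)
})

test_that("parametric fits recover generating parameters", {
  set.seed(302)
  t <- rlnorm(5000, log(400), 0.7)
  fit <- fit_parametric(make_ipd(t, rep(1, 5000)), "AZA", "OS", "lognormal")
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coef[["meanlog"]] - log(400)), 3 * se[1])
  expect_lt(abs(fit$coef[["log_sdlog"]] - log(0.7)), 3 * se[2])
  expect_equal(fit$n_events, 5000L)
  expect_equal(fit$n_censored, 0L)
})

test_that("the exponential MLE equals events over total observed time", {
  set.seed(303)
  t <- rexp(2000, 0.004)
  ev <- as.integer(t <= 500)
  tt <- pmin(t, 500)
  fit <- fit_parametric(make_ipd(tt, ev), "AZA", "OS", "exponential")
  # closed-form right-censored MLE
  expect_equal(natural_params(fit)$rate, sum(ev) / sum(tt), tolerance = 1e-4)
})

test_that("fewer than two events is an insufficient-data error", {
  expect_error(fit_parametric(make_ipd(c(3, 5), c(1, 0)), "AZA", "OS",
                              "lognormal"),
               "insufficient")
})

test_that("select_family takes the minimum-AIC model with ordered ties", {
  m <- function(family, loglik) {
    cf <- if (family == "exponential") c(log_rate = -5) else
      switch(family, lognormal = c(meanlog = 6, log_sdlog = 0),
             c(log_shape = 0, log_scale = 6))
    surv_par_model(family, cf, loglik = loglik, n_events = 10, n_censored = 0)
  }
  # 2-parameter models: AIC = 4 - 2 ll; pick the highest log-likelihood
  cands <- list(m("weibull", -48), m("lognormal", -47), m("loglogistic", -49.5))
  expect_equal(select_family(cands)$family, "lognormal")
  expect_equal(select_family(cands[1])$family, "weibull")
  # exact AIC tie between weibull and lognormal: canonical order wins
  expect_equal(select_family(list(m("lognormal", -48), m("weibull", -48)))$family,
               "weibull")
  expect_error(select_family(list()), "no candidate")
})

test_that("family selection and BIC agree with direct formulas", {
  set.seed(304)
  ipd <- make_ipd(rlnorm(800, 6, 0.8), rep(1, 800))
  fits <- fit_all_families(ipd, "AZA", "OS")
  expect_setequal(names(fits), c("exponential", "weibull", "lognormal",
                                 "loglogistic"))
  aics <- vapply(fits, aic, numeric(1))
  expect_equal(select_family(fits)$family, names(which.min(aics)))
  expect_equal(select_family(fits, criterion = "BIC")$family,
               names(which.min(vapply(fits, function(f) {
                 length(f$coef) * log(800) - 2 * f$loglik
               }, numeric(1)))))
})

test_that("survival_at honours the closed forms of every family", {
  models <- list(exp_model(0.003), wb_model(1.4, 500), ln_model(6, 0.8),
                 surv_par_model("loglogistic",
                                c(log_shape = log(1.5), log_scale = log(400))))
  for (m in models) {
    expect_identical(survival_at(m, 0), 1)
    s <- survival_at(m, seq(0, 20000, by = 50))
    expect_true(all(diff(s) <= 0))
  }
  expect_equal(survival_at(ln_model(log(365), 0.8), 365), 0.5)
  # quadrature oracle: S(t) = 1 - integral of the density on [0, t]
  t <- 400
  expect_equal(survival_at(exp_model(0.004), t),
               1 - integrate(dexp, 0, t, rate = 0.004)$value,
               tolerance = 1e-7)
  expect_equal(survival_at(ln_model(6, 0.8), t),
               1 - integrate(dlnorm, 0, t, meanlog = 6, sdlog = 0.8)$value,
               tolerance = 1e-7)
  expect_error(survival_at(exp_model(0.004), -1), "non-negative")
})

test_that("per-cycle transition reduces to a single risk when AML hazard is zero", {
  os <- ln_model(log(700), 0.9)
  tr <- per_cycle_transition(os, null_model(), cycle_index = 3)
  expect_equal(tr$p_aml, 0)
  expect_equal(tr$p_death, 1 - survival_at(os, 140) / survival_at(os, 105))
  expect_false(tr$absorbed)
})

test_that("equal exponential hazards split the exit probability equally", {
  m <- exp_model(0.002)
  tr <- per_cycle_transition(m, m, cycle_index = 10)
  expect_equal(tr$p_death, tr$p_aml)
  expect_equal(tr$p_death + tr$p_aml, 1 - exp(-2 * 0.002 * 35))
})

test_that("per-cycle transitions match a Monte-Carlo competing-risks oracle", {
  l1 <- 0.004; l2 <- 0.002
  tr <- per_cycle_transition(exp_model(l1), exp_model(l2), cycle_index = 0)
  set.seed(305)
  n <- 1e6
  td <- rexp(n, l1); ta <- rexp(n, l2)
  exit <- pmin(td, ta) < 35
  p_death_mc <- mean(exit & td < ta)
  p_aml_mc <- mean(exit & ta <= td)
  se <- sqrt(p_death_mc * (1 - p_death_mc) / n)
  expect_lt(abs(tr$p_death - p_death_mc), 3 * se)
  se <- sqrt(p_aml_mc * (1 - p_aml_mc) / n)
  expect_lt(abs(tr$p_aml - p_aml_mc), 3 * se)
})

test_that("an exhausted OS curve flags cohort absorption", {
  # Weibull with scale 1 day: S(35) is numerically 0 well before cycle 5
  m <- wb_model(3, 1)
  tr <- per_cycle_transition(m, null_model(), cycle_index = 5)
  expect_true(tr$absorbed)
  expect_equal(tr$p_death, 1)
  expect_equal(tr$p_aml, 0)
  expect_error(per_cycle_transition(m, m, -1), "cycle_index")
})

test_that("conditional survival telescopes across cycles", {
  for (m in list(ln_model(log(600), 0.9), wb_model(1.3, 500), exp_model(0.003))) {
    t_grid <- (0:60) * 35
    s <- survival_at(m, t_grid)
    expect_equal(prod(s[-1] / s[-61]), survival_at(m, 60 * 35) / 1,
                 tolerance = 1e-10)
  }
})

test_that("fitted models serialize to JSON and back exactly", {
  set.seed(306)
  fit <- fit_parametric(make_ipd(rlnorm(300, 6, 0.8), rep(1, 300)),
                        "AZA", "OS", "lognormal")
  path <- withr::local_tempfile(fileext = ".json")
  surv_model_to_json(fit, path)
  back <- surv_model_from_json(path)
  expect_equal(back$coef, fit$coef)
  expect_equal(back$vcov, fit$vcov, ignore_attr = TRUE)
  expect_equal(back$loglik, fit$loglik)
  expect_equal(back$family, fit$family)
})
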