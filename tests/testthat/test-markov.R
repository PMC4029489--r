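test_that("discount factors follow the annual closed form", {
  cfg <- model_config()
  expect_identical(discount_factor(0, cfg), 1)
  # a cycle index whose elapsed time is exactly one year
  expect_equal(discount_factor(365.25 / 35, cfg), 1 / 1.03)
  cfg0 <- model_config(discount_rate = 0)
  expect_true(all(discount_factor(0:100, cfg0) == 1))
  # two years discounts twice
  expect_equal(discount_factor(2 * 365.25 / 35, cfg), 1 / 1.03^2)
})

test_that("one Markov step moves mass as specified and conserves it", {
  expect_equal(unname(markov_step(c(1, 0, 0), 0, 0, 0)), c(1, 0, 0))
  # constant per-cycle AML mortality
  expect_equal(unname(markov_step(c(0, 1, 0), 0, 0, 0.135)),
               c(0, 0.865, 0.135))
  set.seed(401)
  for (i in 1:1000) {
    st <- diff(c(0, sort(runif(2)), 1))        # random occupancy summing to 1
    pd <- runif(1); pa <- runif(1, 0, 1 - pd); pda <- runif(1)
    nxt <- markov_step(st, pd, pa, pda)
    expect_true(abs(sum(nxt) - 1) < 1e-12)
    expect_true(nxt[["dead"]] >= st[3])
  }
  expect_error(markov_step(c(1, 0, 0), 0.7, 0.6, 0), "exceed 1")
  expect_error(markov_step(c(1, 0, 0), -0.1, 0, 0), "probabilities")
})

test_that("an AML-only cohort reproduces the geometric sojourn closed form", {
  arm <- arm_spec("X", null_model(), null_model(), null_model(),
                  costs = flat_bundle(0, 0, 0),
                  utility_mds = 0.67, utility_aml = 0.52)
  cfg <- model_config(discount_rate = 0, epsilon = 0)
  tr <- suppressWarnings(run_cohort(arm, cfg, init_state = c(0, 1, 0)))
  res <- accumulate(tr)
  # mean sojourn of a geometric exit with p = 0.135 is 1/p cycles
  expect_equal(res$ly, (1 - 0.865^520) / 0.135 * 35 / 365.25,
               tolerance = 1e-12)
  expect_equal(res$ly, 1 / 0.135 * 35 / 365.25, tolerance = 1e-6)
  expect_equal(res$qaly, 0.52 * res$ly, tolerance = 1e-12)
})

test_that("a transition-free cohort accrues utility linearly to the cap", {
  arm <- arm_spec("X", null_model(), null_model(), null_model(),
                  costs = flat_bundle(0, 0, 0), utility_mds = 0.67)
  cfg <- model_config(discount_rate = 0, epsilon = 0, max_cycles = 10)
  expect_warning(tr <- run_cohort(arm, cfg), "cap")
  expect_true(attr(tr, "truncated"))
  expect_equal(accumulate(tr)$qaly, 0.67 * 10 * 35 / 365.25)
  expect_equal(accumulate(tr)$ly, 10 * 35 / 365.25)
})

test_that("accumulate sums discounted increments (identity and empty cases)", {
  empty <- structure(data.frame(cycle = integer(), mds = numeric(),
                                aml = numeric(), dead = numeric(),
                                on_frac = numeric(), cost = numeric(),
                                cost_disc = numeric(), ly_disc = numeric(),
                                qaly_disc = numeric()),
                     class = c("cohort_trace", "data.frame"), arm = "X")
  expect_equal(accumulate(empty)$cost, 0)
  expect_equal(accumulate(empty)$qaly, 0)
  one <- empty
  one[1, ] <- list(0L, 1, 0, 0, 1, 100, 97, 0.09, 0.06)
  expect_equal(accumulate(one)$cost, 97)
  expect_equal(accumulate(one)$ly, 0.09)
  expect_equal(accumulate(one)$qaly, 0.06)
  # totals agree with extended-precision summation
  tr <- suppressWarnings(run_cohort(test_arm(), model_config()))
  kahan <- function(x) { s <- 0; c <- 0
    for (v in x) { y <- v - c; t <- s + y; c <- (t - s) - y; s <- t }; s }
  expect_equal(accumulate(tr)$cost, kahan(tr$cost_disc), tolerance = 1e-9)
})

test_that("occupancy is conserved every cycle and death is absorbing", {
  tr <- suppressWarnings(run_cohort(test_arm(), model_config()))
  expect_true(all(abs(tr$mds + tr$aml + tr$dead - 1) < 1e-12))
  expect_true(all(diff(tr$dead) >= 0))
  expect_true(all(tr$mds >= 0 & tr$aml >= 0 & tr$dead >= 0))
  expect_true(all(tr$cost_disc <= tr$cost + 1e-12))
  # the on-treatment fraction is the cessation curve at cycle start
  expect_equal(tr$on_frac, survival_at(test_arm()$cess_model, tr$cycle * 35))
})

test_that("single-session arms are costed on treatment for one cycle only", {
  arm <- test_arm(arm = "SDC", utility_mds = 0.66, single_session = TRUE)
  tr <- suppressWarnings(run_cohort(arm, model_config()))
  expect_equal(tr$on_frac[1], 1)
  expect_true(all(tr$on_frac[-1] == 0))
})

test_that("QALYs equal life-years when utilities are 1 and discounting is off", {
  arm <- arm_spec("X", ln_model(log(500), 0.8), ln_model(log(600), 0.8),
                  wb_model(1.2, 300), costs = flat_bundle(),
                  utility_mds = 1, utility_aml = 1)
  tr <- suppressWarnings(run_cohort(arm, model_config(discount_rate = 0)))
  res <- accumulate(tr)
  expect_identical(res$qaly, res$ly)
})

test_that("raising death hazards never increases total life-years", {
  base <- accumulate(suppressWarnings(run_cohort(test_arm(), model_config())))
  # higher AML mortality
  worse <- accumulate(suppressWarnings(
    run_cohort(test_arm(), model_config(aml_mortality = 0.25))))
  expect_lte(worse$ly, base$ly)
  set.seed(402)
  for (i in 1:5) {
    # uniformly faster OS clock: scale the median down
    f <- runif(1, 0.3, 0.95)
    arm2 <- test_arm(); arm2$os_model <- ln_model(log(700 * f), 0.9)
    expect_lte(accumulate(suppressWarnings(
      run_cohort(arm2, model_config())))$ly, base$ly)
  }
})

test_that("totals are insensitive to the horizon epsilon at defaults", {
  # exponential hazards so the alive fraction actually crosses epsilon
  arm <- arm_spec("X", exp_model(0.008), exp_model(0.004), wb_model(1.2, 300),
                  costs = flat_bundle(4911.24, 1627.78, 1851.86))
  a <- accumulate(run_cohort(arm, model_config(epsilon = 1e-6)))
  b <- accumulate(run_cohort(arm, model_config(epsilon = 5e-7)))
  expect_lt(abs(a$ly - b$ly) / a$ly, 1e-4)
  expect_lt(abs(a$cost - b$cost) / a$cost, 1e-4)
  expect_lt(abs(a$qaly - b$qaly) / a$qaly, 1e-4)
})

test_that("the half-cycle correction shrinks accruals of a shrinking cohort", {
  plain <- accumulate(suppressWarnings(run_cohort(test_arm(), model_config())))
  hcc <- accumulate(suppressWarnings(
    run_cohort(test_arm(), model_config(half_cycle_correction = TRUE))))
  expect_lt(hcc$ly, plain$ly)
  expect_lt(hcc$cost, plain$cost)
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(discount_rate = -0.1), "discount_rate")
  expect_error(model_config(aml_mortality = 1.2), "aml_mortality")
  expect_error(model_config(cycle_days = 0), "cycle_days")
  expect_error(model_config(max_cycles = 0), "max_cycles")
  expect_error(arm_spec("X", null_model(), null_model(), null_model(),
                        flat_bundle(), utility_mds = 1.2), "utilities")
  expect_error(run_cohort(test_arm(), model_config(),
                          init_state = c(0.5, 0, 0)), "sum to 1")
})
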