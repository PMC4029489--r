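---
title: "Methods: a lifetime Markov cohort cost-effectiveness model for azacitidine in high-risk MDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime Markov cohort cost-effectiveness model for azacitidine in high-risk MDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscea)
```

## The decision problem and the model

High-risk myelodysplastic syndrome (MDS) is managed with azacitidine (AZA)
or one of three conventional care regimens (CCR): best supportive care
(BSC), low-dose chemotherapy (LDC) or standard-dose chemotherapy (SDC).
`mdscea` implements a lifetime cost-effectiveness model of that choice from
a national-health-system perspective, in 2012 euros.

The engine is a deterministic Markov cohort model with three mutually
exclusive health states — MDS, acute myeloid leukaemia (AML) and death — on
a five-week (35-day) cycle. The cohort starts in MDS on first-line
treatment. Each cycle, MDS occupants may die or progress to AML; AML
occupants die with a constant probability of 0.135 per cycle, identical
across arms, and receive BSC-pattern management only. Being on or off
first-line treatment is not a separate transition state: the fraction of
MDS occupants still on treatment follows the fitted treatment-cessation
curve, and weights the on- versus off-treatment per-cycle costs. This
mirrors how the treatment phase affects resource use but not utility; no
on/off utility difference is modelled.

Per cycle, with occupancy $(m_t, a_t, d_t)$ and on-treatment fraction
$w_t = S_{\text{cess}}(35t)$:

* cost increment: $m_t\,[w_t c_{\text{on}} + (1-w_t) c_{\text{off}}] + a_t c_{\text{AML}}$,
* life-years: $(m_t + a_t) \cdot 35/365.25$,
* QALYs: $(m_t u_{\text{MDS}} + a_t u_{\text{AML}}) \cdot 35/365.25$,

all multiplied by the cycle-start discount factor $(1+r)^{-35t/365.25}$
with $r = 0.03$ for both costs and effects.

## Survival inputs and extrapolation

Two-year, right-censored trial curves are fitted per arm and endpoint by
maximum likelihood (`flexsurv` under the hood) to four candidate families:
exponential, Weibull, log-normal and log-logistic. "Logistic" in the
health-economic family lists is read as log-logistic, since a plain
logistic distribution admits negative event times. The best fit is chosen
by AIC (BIC is available via `select_family(criterion = "BIC")`); ties go
to the most parsimonious family in the canonical order. Extrapolation
beyond follow-up is the fitted closed form itself, with no hazard capping —
the only long-term guard is the cohort model's horizon rule. Overall
survival and time to AML are typically best described by the log-normal
family here; treatment cessation is fitted as Weibull.

Cycle transition probabilities come from conditional survival over the
cycle $[t_0, t_1)$: $q = 1 - S(t_1)/S(t_0)$ for each endpoint. The two
exits from MDS are combined assuming independent cause-specific hazards:
total exit $1-(1-q_{\text{death}})(1-q_{\text{AML}})$, split in proportion
to the cause-specific cumulative-hazard increments
$-\log(1-q)$. For exponential hazards this reduces exactly to the
$\lambda_i/\sum\lambda_j$ split; the unit tests verify it against a
Monte-Carlo competing-risks simulation. The independence assumption is a
convention — nothing in the published record identifies the joint law —
and is the main structural uncertainty in this step.

## Costing

Per-cycle state costs are assembled from unit costs, drug regimens and
annualised adverse-event (AE) rates, and the packaged tables carry the
printed per-cycle decomposition of the four arms (MDS on treatment, MDS
off treatment, AML) to the cent.

Choices worth stating explicitly:

* **Body-surface area.** The mg/m² regimen arithmetic needs a BSA that the
  cost tables do not print. We adopt **1.70 m²**, back-calculated from the
  low-dose cytarabine row (48.38 euro ÷ (0.0271 × 150 × 7) ≈ 1.700).
  Implied BSA across the other printed rows varies between 1.687 and
  1.700, so the printed per-cycle pharmacology values are carried as the
  canonical inputs and the formula is kept for new regimens.
* **Wastage.** Although vial wastage is the stated costing assumption, the
  printed costs match exact-milligram arithmetic, so `wastage_mode =
  "none"` is the default and `"vial_round_up"` (with configurable vial
  sizes) is available for sensitivity analyses.
* **SDC administration.** The printed SDC administration cost
  (16,344.02 euro per cycle) is below 28 inpatient days × 742.91 euro;
  it is taken as printed rather than re-derived.
* **SDC single session.** Only one SDC session is costed: the on-treatment
  fraction is forced to zero from the second cycle onwards
  (`single_session = TRUE`).
* **AEs.** On-treatment AE costs are inside the printed on-treatment
  components; off-treatment and AML states carry the annualised
  BSC-pattern AE line (345.81 euro per cycle), which the printed state
  totals require as a per-cycle component. `ae_cost_per_cycle()` converts
  annual AE rates to the 35-day cycle for user-built bundles.
* Two printed per-cycle costs coexist for BSC (1,426.21 on treatment,
  1,772.02 off treatment); the running text quotes the off-treatment
  figure as "the" BSC cycle cost. Both are carried.

## Incremental analysis and the pooled comparator

`incremental()` computes $\Delta C$, $\Delta LY$, $\Delta QALY$ and the
ICERs, leaving an ICER undefined (rather than infinite) at zero effect
difference, and flags dominance. `threshold_decision()` applies the net
monetary benefit rule $\text{NMB} = \lambda\,\Delta QALY - \Delta C$ at a
willingness to pay of 50,000 euro/QALY by default.

The pooled "AZA vs CCR" comparison weights the comparator arms by the
trial's treatment pattern (110/79/38/20 patients). Two interpretations are
implemented: `weight_outcomes` (count-weighted means of per-arm lifetime
cost/LY/QALY, then one incremental comparison — the default, because it
yields a coherent pooled arm for the PSA) and `weight_icers`
(count-weighted mean of the pairwise ICERs). The published pooled row is
reproduced by neither mode exactly — ICER-weighting of the printed
pairwise ratios comes closest (within 0.4%) — so the printed values are
carried verbatim in `printed_lifetime_results()` and the pooling mode is
an explicit argument, not a hidden constant.

## Probabilistic sensitivity analysis

`run_psa()` propagates parameter uncertainty by parametric Monte-Carlo:
each draw samples

* survival, time-to-AML and cessation coefficients from their joint
  asymptotic multivariate normal on the estimation scale, using the fit
  covariance;
* utilities and the per-cycle AML mortality from beta distributions
  moment-matched to the central value with a ±30% interval read as a 95%
  interval ($sd = 0.3\,\mu/1.96$), truncated to keep the beta feasible;
* every per-cycle cost component from a normal with the same ±30%-as-95%
  reading, floored at zero.

The ±30% band operationalises "no uncertainty estimate available"; which
parameters carry empirical covariance versus the assumed band is explicit
in the inputs rather than hard-coded. The AE line inside the packaged
bundles is sampled as a cost component (normal); users who build bundles
from AE *rates* can sample those as betas and re-assemble. The reference
analysis size is 50,000 draws of the cohort model (a parameter-level
Monte-Carlo, not a patient-level microsimulation); tests and examples use
hundreds to a few thousand draws. Failed draws are excluded and counted,
and more than 5% failures aborts the run. `ceac()` recounts positive net
monetary benefit per willingness-to-pay point.

## The synthetic trial generator

The patient-level data behind the published curves are unavailable, so
`generate_ipd()` simulates pseudo individual-patient data with exactly the
structure the pipeline assumes: per arm, log-normal overall survival,
log-normal time to AML, Weibull time to treatment cessation, all
independently drawn per patient and administratively censored at 730 days.
Arm sizes default to the trial's 110/79/38/20 pattern.

Because only the *gains* in median OS are published (12.9, 9.1 and 8.7
months for AZA over BSC, LDC and SDC respectively — 9.4 overall), absolute
anchors are a package choice made once: AZA median OS 24.5 months
(a plausible figure for azacitidine responders in this population),
comparator medians set by subtracting the printed gains, `sigma_log` 0.9
(a typical heavy right tail for these curves), time-to-AML medians of
17.8 months (AZA) and 9.5–10.5 months (CCR arms), and cessation medians of
roughly 9 cycles for AZA, shorter for the comparators. These defaults are
the package's study conditions for testing, not a reconstruction of the
trial: passing tests demonstrate that the pipeline recovers the generating
process and obeys its invariants, not that it reproduces the published
lifetime totals, which depend on unpublished fitted parameters and are
deliberately **not** regeneration targets. Real-data features the
generator does not emulate: OS/AML correlation within patients, visit-time
rounding, covariates, and response-dependent cessation.

## Numerical choices and degenerate inputs

* Horizon: `epsilon = 1e-6` alive fraction, cap 520 cycles (~50 years).
  With heavy-tailed log-normal fits the cap can bind; the trace then
  carries a truncation flag and a warning. Doubling the epsilon precision
  moves totals by less than $10^{-4}$ relative.
* Half-cycle correction defaults **off**: the printed per-cycle sums and
  lifetime totals are consistent with cycle-start accrual. A standard
  start/end-mean option is provided (`half_cycle_correction = TRUE`).
  Accrual timing (start vs mid vs end of cycle) is not stated in the
  published record; cycle-start is this package's documented choice.
* Transitions apply at cycle end; costs and utilities accrue on
  cycle-start occupancy.
* An exhausted OS curve ($S(t_0) = 0$) absorbs the cohort:
  `per_cycle_transition()` returns `p_death = 1` with an `absorbed` flag.
* Zero-hazard endpoints are representable (a rate of `1e-300` keeps
  estimation-scale coefficients finite) and reduce the competing-risk
  split to the single-risk formula exactly.
* Model selection fits each arm separately (no shared shape parameters);
  whether the original analysis shared parameters across arms is unknown.
* Seeds: `generate_ipd()` is bit-reproducible given the scenario seed and
  restores the caller's RNG stream; `run_psa(seed =)` makes the PSA
  reproducible end to end.

## Problem sizes used by the test suite

Distributional checks use n = 20,000 draws (Kolmogorov–Smirnov distance
< 0.02, parameter recovery within 2%); family selection is verified on 100
replicates of n = 5,000; the cohort engine is validated against a
100,000-patient individual-level microsimulation within three Monte-Carlo
standard errors and against closed forms (geometric AML sojourn, discount
factors) at $10^{-9}$ relative; PSA checks use 200–2,000 draws. These
sizes were chosen so the full suite runs in a couple of minutes while
keeping Monte-Carlo error well below every asserted tolerance.

## Known limitations

* The published lifetime totals and PSA probabilities (96.49% at 50,000
  euro/QALY vs CCR, 83.21% vs BSC, 91.21% vs LDC) require the unpublished
  fitted survival parameters and are documented as non-reproducible; the
  package reproduces the published *derived* quantities (increments,
  ICERs, per-cycle costs) from the printed inputs instead.
* No age-dependent background mortality, tunnel states, or covariate
  adjustment; interval censoring and cure/spline extrapolations are out of
  scope.
* The on/off-treatment split affects costs only, matching the source
  model; if treatment also shifted utility the QALY totals would change.
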