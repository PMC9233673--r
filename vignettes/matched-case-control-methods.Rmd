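---
title: "Methods: matched case-control analysis of post-vaccination carditis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched case-control analysis of post-vaccination carditis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vaxcarditis)
```

## The design and its estimand

The package implements a matched case-control study of acute myocarditis
and pericarditis following mRNA Covid-19 vaccination in a population aged
12–50 over a roughly six-month observation window (May 12 – October 31
2021 under the defaults). Each hospitalized case is matched at its
admission date (the *index date*) to 10 controls sharing sex, completed age
in years and department of residence, drawn by simple random sampling
without replacement. Exposure is the nine-level classification of the most
recent vaccine dose relative to the index date — brand × dose rank ×
window, with risk windows 1–7 and 8–21 days; a dose more than 21 days back,
or none, is "unexposed".

Conditioning on the matched set removes confounding by the matching
variables; the conditional logistic model then estimates within-set odds
ratios for the exposure categories and three covariates (5-year carditis
history, 30-day SARS-CoV-2 infection, binarized deprivation). With
hospitalization for carditis a rare event at every exposure level, these
odds ratios approximate rate ratios, which is what licenses both the
matched-sampling scheme and the burden arithmetic below.

## The synthetic registry

Real claims extracts of this kind cannot be redistributed, so the package
generates registries with the statistical structure the analysis assumes:

* **Event model.** Each person-condition pair carries a daily Bernoulli
  hazard `baseline_daily_rate × OR(exposure category on day t) ×
  history × infection(t) × deprivation`. Only the first event per condition
  is kept, becoming a hospital stay coded for the condition. Because the
  hazard is piecewise constant between dose/test change-points, first-event
  days are drawn exactly by truncated-geometric sampling per constant
  segment; this makes a 200,000-person registry a few-second operation.
  With daily risks of order 1e-4 and below, odds ≈ risk ≈ rate, so the
  generator's multiplicative effects are (to very good approximation) the
  conditional odds ratios the fitter should recover — the basis of the
  parameter-recovery and calibration tests.
* **Defaults as study conditions.** The default `true_or` values are the
  published multivariable point estimates for the eight categories (e.g.
  8.1 for BNT162b2 dose 2 and 30 for mRNA-1273 dose 2 in the 1–7 day
  myocarditis window), and the covariate effects 160/9/0.88 (myocarditis)
  and 250/4/0.87 (pericarditis). The population baseline rate default,
  2.5e-7/person-day, is back-solved from the reported ~1600 cases among 32
  million persons over 172 days — the only incidence anchor available.
  Uptake: 75% receive a first dose at a uniform in-window date (brand share
  0.881 BNT162b2, from the national dose totals), with a dose-1→dose-2 gap
  N(28, 5) discretized and floored at 14 days; second doses falling beyond
  the window are not received in it. History prevalence 6e-4 (matching the
  ~0.06% seen among controls) and a 4% chance of a positive test at a
  uniform date reproduce realistic covariate frequencies. Admissions in the
  final study month are unrecorded with probability 1 − 0.78.
* **Desk scaling.** Analyses and tests use tens to hundreds of thousands of
  persons with the baseline rate scaled up in inverse proportion (e.g.
  3e-5 to 6e-5/day), keeping expected case counts in the hundreds to
  thousands. This leaves relative risks, matching structure and coverage
  properties untouched; only absolute burden denominators (doses per
  person) shrink, which is why the worked burden numbers in the README are
  large per 100,000 doses.
* **What is *not* emulated.** Departmental demography is uniform; there are
  no deaths (so the "alive at index date" matching constraint is vacuously
  satisfied), no booster or viral-vector doses, no seasonal or roll-out
  trends in uptake or incidence, and test-negative records are omitted.
  Passing tests therefore demonstrate correctness of the estimator and
  pipeline under the assumed data-generating process, not robustness to
  real-data pathologies such as differential ascertainment.

## Ascertainment, matching, exposure: conventions

* **Code families.** Myocarditis I40.x, I41.x and I51.4; pericarditis I30.x
  and I32.x, matched dot-free by prefix. The first qualifying *recorded*
  admission in the window is the single index date per person per
  condition; unrecorded (reporting-lag) stays are invisible.
* **History windows** are half-open: carditis history in
  `[index − 1826 days, index)` ("five years", fixed day count so the length
  is leap-day invariant) and infection in `[index − 30 days, index)`; an
  admission on the index date is the case event, not history. Covid-coded
  stays count toward the infection flag with a configurable prefix (default
  U07.1) since the code list is a site convention.
* **Eligibility at the index date.** A control must not be a study-window
  case of either condition on or before the index date; a *lifetime* prior
  diagnosis does not disqualify (controls with 5-year history exist in the
  design this mirrors), and future cases may serve as earlier controls —
  the risk-set convention. "Without replacement" is read study-wide per
  condition, the stricter interpretation; cases are processed in index-date
  order so the sampling stream is reproducible. A stratum that cannot
  supply the full ratio fails loudly by default (`on_short = "keep"` opts
  into short sets).
* **Day-count convention.** Exposure uses whole days `d = index − dose`
  with `d ≥ 1`; a same-day dose is unexposed because the windows start at
  day 1. Windows are inclusive at both ends; the classification is
  invariant to translating all dates, which the tests check.

## The conditional-logistic fitter

The exact conditional likelihood (one case per set) is maximized by
Newton–Raphson from β = 0 with analytic gradient and Hessian, step halving
when a step fails to improve, convergence at sup-norm gradient < 1e-8 (or
at the step-halving floor, which in double precision means no improving
step exists — the achieved gradient is then checked against 1e-5).
Per-set log-sum-exp terms are max-shifted for stability and accumulated via
`rowsum`, so a fit on 500 × 11 rows takes milliseconds. Degenerate inputs
are rejected with structural errors: a set without exactly one case, a
column with no within-set variation, a singular information matrix, or
divergence (|β| > 15), which is reported as separation naming the offending
terms. Driver-level fits (subgroups, sensitivity re-runs) catch that
condition and mark the terms "not estimable" instead of failing, mirroring
how sparse subgroup cells are reported in practice.

Wald intervals at ±1.96 se (not profile likelihood) are used because the
report format this mirrors shows log-symmetric intervals. Reference levels:
"unexposed" for the category factor and *most deprived* for the deprivation
indicator (the model column is `least_deprived`). Display rounding of odds
ratios — two significant figures at ≥10, one decimal below — is a
reporting convention only; all arithmetic uses full precision.

The fitter is validated three independent ways: brute-force term-by-term
enumeration of the conditional likelihood, the closed form
β̂ = log(n10/n01) for 1:1 discordant pairs, and coefficient agreement to
1e-6 with the `survival` package's stratified-likelihood implementation,
which serves purely as a test oracle.

## Burden arithmetic

For a category with odds ratio OR and `E_c` exposed cases (final-month
counts divided by the 0.78 completeness first), attributable cases are
`A = E_c (OR − 1)/OR`, clipped at zero. The delta method is applied on the
log-OR scale, where the standard error is natural:
`se(A) = E_c e^{−β̂} se(β̂)`, with `E_c` treated as fixed — the interval
reflects the OR's uncertainty only, and a parametric-bootstrap alternative
(`bootstrap_ci()`) is provided and shown in tests to agree within 2% of
interval width over the relevant parameter range. Excess cases per 100,000
doses and doses per attributable case are exact reciprocals before display
rounding (nearest 1,000 above 100,000 doses/case, nearest 100 below).
Burden is reported only where the adjusted OR's interval excludes 1,
with an override flag, since an attributable count derived from a
non-significant association would suggest spurious precision.

## Open choices made here

* A person may be a case of both conditions with separate index dates, and
  the myocarditis and pericarditis studies are fully independent (a person
  may control in both).
* Subgroup models re-estimate all coefficients within the subgroup rather
  than constraining covariate effects globally, matching the
  independent-interval presentation such analyses use; subgroup sets are
  whole matched sets, which are homogeneous in sex and age by construction.
* No multiple-testing correction is applied across the many subgroup
  intervals; they are reported as per-stratum 95% CIs.
* The registry stores its study window in a small `meta.csv` beside the
  four data tables so a directory round-trips losslessly.

## Problem sizes and numerical checks

The test suite runs entirely on generated data: unit fixtures of a handful
of persons, shared registries of 12,000–30,000 persons, a
1000-replicate coverage study (500 sets of 1:10 at 10% exposure prevalence,
true OR 2.0) for the Wald intervals, and a 100-replicate null-effect
calibration (200 sets each) whose pooled subgroup intervals should cover 1
at roughly the nominal rate — the tolerance there is ±3 percentage points
because per-category exposed-case counts of 2–6 put Wald intervals in their
known small-sample regime. The matching check at full scale (1612 cases,
10:1) uses 200,000 persons across 10 departments, sized so every stratum
holds ~250 persons against a worst-case draw of a few dozen controls.

## Limitations

Synthetic validation cannot speak to coding accuracy, ascertainment bias or
confounding beyond the matched and modelled covariates; the generator's
uptake model is deliberately simple (uniform dose-1 dates rather than a
roll-out curve); and exact conditional inference for very sparse categories
is out of scope — sparse cells are flagged not-estimable rather than handled
by exact methods.
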