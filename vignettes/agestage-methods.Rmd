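---
title: "Methods: age-stage, two-sex life tables in agestage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-stage, two-sex life tables in agestage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestage)
```

## The data model

The unit of observation is one individual followed daily from oviposition
to death. A record stores the completed-stage durations (whole days), the
stage in which death occurred and the days lived in it, the sex (known
only for individuals reaching adulthood), and for females a daily egg
series. Two conventions fix every downstream formula:

* **Age convention.** Age 0 is the day of oviposition, and an individual
  occupies stage *j* on the half-open interval
  [entry age, entry age + duration). Age at death is therefore exactly the
  sum of completed durations plus the days lived in the death stage, and
  "alive at age *x*" means *x* < age at death. This makes the daily census
  and the `(x+1)` exponent of the Euler–Lotka equation unambiguous.
* **Whole days.** Observation is daily, so fractional durations are a
  data error and are rejected at parse time rather than rounded.

Cohorts reared at different temperatures can pass through different
numbers of larval instars (five to seven here). To compare them on one
stage axis, a stage scheme carries an order-preserving many-to-one
grouping map; pooling instars 5–7 into a single analysis stage sums each
individual's durations within the pool and re-assigns deaths inside the
pool (carrying the days already spent in it), so ages at death are
invariant under grouping.

A deliberately absent feature: there is no censoring flag. The records
this design emulates follow every individual to death; individuals lost
to handling cannot be represented and must be excluded upstream.

## Life-table construction

`build_age_stage_survival()` is a literal daily head-count:
`s_xj` = (individuals alive in stage *j* on day *x*)/n0, with the adult
stage split into female and male columns. Every value is a multiple of
1/n0, row sums give `l_x`, and the matrix equals a brute-force per-day
census by construction (and by test, against an independent oracle).

Fecundity enters twice, with different denominators:

* `f_x` divides the day's eggs by the adult females alive that day
  (eggs per female);
* `m_x` divides by all survivors of the day, both sexes
  (eggs per individual).

Both use the 0/0 → 0 convention so schedules extend over the cohort's full
age range. The identity `n0 · Σ l_x m_x` = total eggs laid is exact and is
asserted on synthetic cohorts.

Summary statistics follow the field's reporting conventions: stage
duration means are over individuals that *completed* the stage (a death
inside a stage contributes its days to the census but not to the stage
mean); adult longevity (emergence to death) and entire lifespan (egg to
death) are split by sex; immature mortality is pre-adult deaths over n0,
as a percentage. SE is throughout the sample SD over √n. For
reproduction, APOP is first-egg age minus emergence age, TPOP is
first-egg age from the female's own oviposition, and the oviposition
period defaults to the inclusive first-to-last-egg span — gap days
count — with an `"active"` option counting only laying days, since
published tables rarely state which convention they use.

## Population parameters and the Euler–Lotka solver

`R0 = Σ l_x m_x`, `GRR = Σ m_x`, `λ = e^r`, `T = ln(R0)/r`, and *r*
solves `Σ e^{−r(x+1)} l_x m_x = 1`. The left side is strictly decreasing
in *r*, so the solver brackets the root starting from [−1, 1] per day,
doubling outward until the sign changes, then bisects to a bracket width
of 1e−12; the returned root's residual is checked against 1e−10.
Negative *r* (R0 < 1) needs no special handling. R0 = 0 is an explicit
error — a cohort that never reproduces has no growth rate, and callers
(notably the bootstrap) must treat that case as data, not silently as
NaN.

**Bootstrap.** B resamples of n0 individuals with replacement; the whole
pipeline is rerun per resample; SE = SD of replicates, CI = 2.5/97.5
percentiles (no BCa — the studies this mirrors report plain SEs). The
default is B = 10,000; the bundled analyses use B = 1,000–2,000, which
stabilises the SEs to a few percent. Replicates without reproduction are
counted, kept in the R0/GRR statistics (0 is a real outcome there) and
excluded from r/λ/T, with a warning. Internally the resampling is
implemented as multinomial weights and two matrix cross-products plus a
vectorised bisection, which is algebraically identical to rebuilding each
resampled cohort (a test pins the two paths against each other) but two
orders of magnitude faster.

## The synthetic-cohort generator

`cohort_spec()` describes a stochastic life history whose expected
schedules are computable exactly: per-stage duration pmfs on whole days
and per-stage completion probabilities; death inside a failed stage on a
uniformly drawn day of the drawn duration; a female fraction at
emergence; an APOP pmf; a daily fecundity curve over the oviposition
window; and sex-specific adult-longevity pmfs. Daily egg counts are
Poisson around the curve by default (negative-binomial and deterministic
options exist; published tables give only means, so the simplest count
model is the default). `expected_schedules()` propagates these
distributions by exact convolution — entry-age distributions stage by
stage, a defective death-age distribution, and expected egg production
conditioned on female survival — and `true_params()` applies the very
same parameter definitions to that expectation. `m_x` truth is the ratio
of expectations, i.e. the large-cohort limit of the estimator.

The bundled `study_spec()` family emulates the study design this package
was built around: 150 eggs per constant-temperature treatment (21–36 °C),
5–7 instars depending on temperature, stage-duration pmfs whose means
equal the published per-stage means exactly (floor/ceiling or shifted
binomial discretisations), per-stage survival set so cumulative immature
mortality matches the published percentage (split evenly across immature
stages, since per-stage mortality was not published), a 1:1 sex ratio, a
triangular fecundity curve peaking a third of the way into the published
oviposition period and scaled to the published lifetime fecundity, and at
36 °C an unhatchable egg stage. These specs are *illustrative*: printed
means constrain them, but the shapes and dispersions are modelling
choices, so they reproduce the study's structure (ordering of treatments,
egg failure at 36 °C), not its exact parameter table. What passing tests
on simulated cohorts shows is that the *estimators* recover known truth
under realistic structure — not that real data would match any particular
published value. Real cohorts differ in ways the generator deliberately
omits: day-to-day fecundity autocorrelation, duration–longevity
correlations within individuals, and any deviation from a constant
per-stage daily death hazard within the failed stage.

## Numerical and design choices

* **Log base for the thermal fit.** Development rate is regressed on
  log temperature; R² is base-invariant and the intercept too, while the
  slope scales by ln(base). The default is the natural log, which is the
  base that reproduces the published coefficients for this regression
  even where such equations are written with "lg"; base 10 is an option.
  The fit is on per-temperature mean rates; individual-level fitting is
  possible but not the default, since published anchors are means.
* **Zero within-group variance in ANOVA.** Equal means give F = 0;
  unequal means over constant groups give F = ∞, p = 0 by convention
  (documented, tested).
* **LSD letters.** Pairwise t tests use the pooled MSE with
  `SE = sqrt(MSE(1/n_i + 1/n_j))` for unequal n, and letters come from
  the insert-and-absorb algorithm over means sorted descending
  ('a' = largest). Sharing a letter is exactly equivalent to a
  non-significant pair — an invariant tested on randomised inputs. No
  multiplicity correction is applied beyond LSD itself, matching the
  reporting style this mirrors.
* **Determinism.** Every stochastic entry point (simulation, bootstrap)
  requires a seed and is bit-reproducible given one; the analysis
  drivers write byte-identical outputs on reruns.

## Problem sizes in the shipped tests

The suite exercises: census-oracle equivalence on random cohorts of
n ≤ 20; conservation and sign-law properties on dozens of random
schedules; estimator consistency on one 40,000-egg simulated cohort
(R0 and r within 1% of truth); Monte-Carlo agreement of mean `l_x` with
its expectation over 200 simulated 150-egg cohorts (3 SE bands); and
bootstrap calibration — the 95% percentile CI for r covers the generator
truth in at least 90 of 100 simulated 150-egg cohorts at B = 1,000.
These sizes were chosen as the smallest that make the corresponding
statistical statements sharp.

## Known limitations

* No censoring; records must be complete to death.
* `m_x` truth is a ratio of expectations, so finite-cohort bias of order
  1/n0 exists in principle (invisible at n0 = 150 relative to sampling
  noise).
* The bootstrap treats individuals as exchangeable; block structure
  (e.g. rearing batches) is not modelled.
* The thermal model is a log-linear description over the observed
  temperature range, not a mechanistic (threshold/degree-day) model, and
  should not be extrapolated.
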