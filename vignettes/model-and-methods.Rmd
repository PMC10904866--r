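---
title: "Simulating adherence to diabetic retinopathy screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating adherence to diabetic retinopathy screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drscreensim)
```

## The problem

Diabetic retinopathy (DR) is asymptomatic until late stages, so health
systems screen the diabetic population at regular intervals. The benefit of
a screening program is bounded by adherence: the fraction of issued calls
that end in an attended screening. `drscreensim` simulates a regional DR
screening program as a discrete-time agent-based model (one tick = one
week), with the individual decision to attend modelled explicitly, so that
hypothetical interventions on subgroups can be compared against a paired
baseline before anyone spends money on them.

Every agent is a diabetic with demographics (age, gender, subregion of
residence, income, education, degree of urbanization, occupation, a
demographic cluster label) and a screening history (times called, times
attended, percent prior adherence, last screening result). The program
itself contributes strategy variables: call-notice lead time, expected
waiting time on the day, reminder intensity, and the difficulty of reaching
the screening location.

## The weekly state machine

Agents cycle through four states: *not called* → *called* → *attended* /
*did not attend* → *not called*. A call letter is issued when the
simulation week reaches the agent's scheduled call week; `notice_weeks`
(default 4) later, on the screening date, the decision engine is invoked.
Attenders receive a screening outcome; both branches increment the call
counter, recompute percent prior adherence (a missed call counts in the
denominator), and are re-scheduled `interval_weeks` (default 52) after the
previous call, so successive calls — and successive screening dates — are
exactly one interval apart. The default run is 10 cycles × 52 weeks = 520
weekly steps over 10,000 agents, with 5 replicate runs; these sizes are the
package defaults and are what the reporting layer summarizes.

Screening outcomes are drawn, by default, from the program's marginal
distribution: 4% positive, 93% negative, 3% inconclusive. A diagnostic mode
is also provided for experiments where the latent disease state matters: a
disease indicator is drawn at `disease_prevalence`, the test is positive
with probability `sensitivity` (0.96) when disease is present and
`1 - specificity` (0.06) otherwise, and non-positive results are recorded
as inconclusive with probability $0.03/0.96$ so the marginal inconclusive
rate is preserved. We deliberately carve the inconclusive mass out of the
negative branch only: overlaying it on all results would make the positive
rate among diseased agents $0.97 \times 0.96$, contradicting the printed
test sensitivity.

## The decision engines

### Logistic engine

The logistic engine scores the decision from screening history only:

$$\operatorname{logit} p = \beta_0
  + \beta_1\,\text{pct\_prior\_adherence}
  + \beta_2\,\text{times\_called}
  + \gamma_{\text{last result}}$$

with `last_result` indicator-coded against the reference level "none"
(never screened). The number of times called includes the current call, so
the feature is at least 1 at decision time, while percent prior adherence
is computed over resolved calls only.

The original regression this engine mirrors was estimated on a
confidential regional call registry and its numeric coefficients are not
publicly available, so the package ships synthetic defaults chosen once:
signs follow the reported directions (prior adherence and call count up,
previous positive result down relative to negative), the `times_called`
effect (0.08 per call) is large enough to be recoverable by the
calibration procedure below at realistic sample sizes (the test suite
checks recovery at n = 20,000), and the intercept (−0.70) is calibrated so the default
10-cycle simulation converges at a cumulative adherence near the observed
program level (about 67–68%). The same coefficients are the ground truth
of the synthetic call-record generator, which keeps the engine, the
generator and the calibration procedure mutually consistent.

### Fuzzy engine

The fuzzy engine implements a Mamdani inference system with three
Health-Belief-Model components — *access barriers* (age, income,
screening-location difficulty, degree of urbanization), *knowledge of the
disease* (age, education, percent prior adherence), and *quality/strategy
of the screening program* (reminder intensity, waiting time, call-notice
lead time). Every variable has a binary linguistic partition
(easy/difficult or high/low) built from three membership shapes: a line
through two anchor points clamped to $[0,1]$, a peak-normalized Gaussian
$\exp(-(x-c)^2/2\sigma^2)$, and the pointwise maximum of two Gaussians
with a shared spread. The Gaussians are fuzzy memberships normalized to
peak 1, not probability densities — read as densities, the stated spreads
(e.g. sd 17,000 on income) would give memberships near zero everywhere.

Rule bases are generated from an at-least-half template: one rule per
combination of binary labels ($2^4 + 2^3 + 2^3 = 32$ rules), with
consequent "strong" adherence propensity when at least $\lceil n/2 \rceil$
of the inputs carry their favorable label. Inference is standard Mamdani:
minimum for AND, activation clips the consequent set, clipped sets combine
by pointwise maximum, and the crisp component score is the centre of
gravity of the aggregate, computed by the trapezoid rule on 1001 evenly
spaced points of the $[0,100]$ output domain (discretization error is far
below reporting precision; the test suite checks agreement with a
100,001-point brute-force oracle to within 0.1). An identically-zero
aggregate falls back to the domain midpoint (50) rather than crash a
population run. Out-of-domain crisp inputs are clamped with a warning.

The consequent terms are not specified in any source we could use, so the
output variable "adherence propensity" uses the ramp pair strong
$= x/100$, weak $= 1 - x/100$, mirroring the dominant input shapes. A
consequence worth knowing: the centroid of any max-combination of these
two clipped ramps lies in $[33.3, 66.7]$, so the pure fuzzy engine
compresses probabilities toward the middle; averaging the three component
scores and dividing by 100 gives the fuzzy probability, to which zero-mean
uniform noise of magnitude `variability` is added (clipped to $[0,1]$).

### Combined engine and the decision draw

The combined mode takes a weighted mean of the two probabilities (default
50/50). The final decision is, by default, a Bernoulli draw at the decision
probability: only a stochastic draw produces the replicate-to-replicate
standard deviations (a few tenths of a percent on 10,000 agents) that make
confidence-interval reporting meaningful. A hard-threshold policy is
provided for deterministic what-if runs.

## The synthetic population

The registry that motivated this model (271,867 calls, 108,620 diabetics
across 8 subregions of northern Portugal) is not public, so the package
generates a synthetic population with the same *structure*: 8 named
subregions whose shares reproduce the published 66.41% / 33.59% split
between the five training and three testing subregions; two demographic
clusters (cluster 1 younger and mostly active, cluster 2 older and mostly
retired, shares 50.9/49.1); truncated-normal ages per cluster
(means 48 and 72); median-parameterized log-normal incomes and Beta
urbanization per subregion; Beta education scores per cluster; and initial
screening histories (30% never called; the rest with $1 +
\text{Poisson}(2)$ prior calls and per-call attendance probability 0.66,
near the registry-wide adherence level). All of these are editable,
clearly synthetic parameterizations: passing tests on this population
demonstrates the machinery and its statistical properties, not that the
synthetic region reproduces the real one. In particular the published
per-subregion adherence rates are shipped only as a reference column for
report flagging (`reference_adherence()`), never as generator inputs, and
no test asserts agreement with them.

What the generator does not emulate: spatial autocorrelation within
subregions, household structure, attrition/mortality, disease progression,
and any correlation between income and screening history at baseline.

## Calibration from call records

`fit_stepwise_logistic()` reproduces the variable-selection step that
produced the original three-predictor equation: forward stepwise selection
by likelihood-ratio p-value over 21 candidate covariates (enter at
p < 0.05, remove at p > 0.10), with accuracy and rank-based AUC reported
on a 30% holdout. `simulate_call_records()` generates registry-like call
records in which only the three history predictors carry effects; the 18
inactive covariates are correlated through two latent axes (age/frailty
and socioeconomic status), as administrative covariates are in practice.

A property of the prescribed procedure worth stating plainly: with 18 null
candidates each tested at $\alpha = 0.05$, the probability that at least
one noise covariate enters is appreciable (on the order of one minus
$0.95^{k}$ for $k$ effectively independent candidates), so the *count* of
selected covariates is a random variable concentrated on 3 but with mass
on 4–5. The three true predictors themselves are recovered essentially
always at n = 20,000, and their coefficients land within sampling error of
the generating values; the test suite asserts exactly that.

## Scenarios

Interventions modify decision probabilities for selected agents and
nothing else. Three presets ship with the package: setting the decision
probability of agents with a previous positive result to 0.95; adding 5
percentage points for agents who have attended at least once; adding 20
percentage points for students under 25. Stated percentage increases are
read as percentage points added to the probability (a multiplicative
action is also available); "set" overrides, and multiple scenarios compose
left to right. Selector effects persist as long as the selector holds,
re-evaluated at each decision. Comparisons run both arms on the same
population and seed; because all agents share one random stream,
probabilities outside the selector are bitwise-identical in the first
cycle and statistically identical afterwards (histories diverge only
through the intervention's own effect), which is what the locality tests
check.

## Reporting

Replicate summaries report per-subregion means and sample standard
deviations of the final cumulative adherence rates, with Student-t
intervals on $n-1$ degrees of freedom at 95% and 99%. The t interval is a
deliberate, documented choice: the printed intervals in the source
material are asymmetric around their means and match no standard formula,
so they were not reverse-engineered. When a reference column is supplied,
values outside each interval are flagged, mirroring the published table's
bold-cell convention.

## Numerical and degenerate-input choices

* COG discretization: 1001 points, trapezoid rule; midpoint fallback for a
  zero aggregate; centroid is scale-free in the grid weights.
* Membership evaluation clamps crisp values to the variable domain (with a
  warning) rather than extrapolate.
* Weights of the combined mode must sum to 1 within $10^{-9}$; marginal
  outcome probabilities likewise.
* `notice_weeks` must be strictly less than `interval_weeks`; a zero-cycle
  run returns an empty, well-formed event log.
* Replicate seeds are drawn by `sample.int()` from the base seed, so a
  replicate set is a pure function of the base seed.
* All agents are called in week 0 by default (each diabetic is called at
  the start of the program); `stagger_first_call` spreads first calls
  uniformly over one interval for steady-state experiments.

## Problem sizes

The shipped defaults (10,000 agents, 10 cycles, 5 replicates) run in
seconds for the logistic engine and well under a minute per replicate for
the fuzzy engine on a single core. The test suite uses smaller populations
(hundreds of agents, 1–4 cycles) for end-to-end properties and the full
default size where the property is about the defaults themselves
(law-of-large-numbers and intervention checks).

## Known limitations

* The fuzzy engine's output compression (scores in roughly [33, 67]) is a
  structural consequence of the two-ramp consequent; real populations with
  extreme adherence subgroups will be pulled toward the middle.
* No disease progression: outcomes do not feed back into risk, and
  "inconclusive" results do not trigger early re-calls.
* Non-attenders are re-called on the same fixed interval as attenders.
* The synthetic population is structurally, not statistically, faithful to
  the original registry; regional rate comparisons against the shipped
  reference column are illustrative only.
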