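---
title: "Modelling disease progression and designing responder-based trials with cnmbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disease progression and designing responder-based trials with cnmbayes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cnmbayes` models longitudinal bounded clinical scores from a
natural-history study (NHS) of centronuclear myopathy and turns the model
into a single-arm trial design in which each patient acts as their own
control. This vignette explains the model and its assumptions, the
choices behind the defaults, and what the synthetic-data machinery does
and does not establish.

## The progression model

A bounded score (FEV1 percent predicted, time on ventilator, motor
scales) is linearly rescaled to the unit interval and modelled as

$$y_{ij} \sim \mathrm{Beta}(\mu_{ij}\nu,\ (1-\mu_{ij})\nu), \qquad
  \mathrm{logit}(\mu_{ij}) = \alpha_i + \beta_i (T + t_j),$$

where $i$ indexes patients, $t_j$ is time in months since the patient's
first visit, and $T$ centres time (default $-\bar t$ over the dataset, so
the intercept is interpreted mid-window and intercept/slope posterior
correlation is reduced). The beta "sample size" $\nu$ gives
$\mathrm{Var}[y] = \mu(1-\mu)/(1+\nu)$: visit-to-visit variability that
shrinks automatically near the bounds, which is what keeps predictions
inside the feasible score range.

Assumptions worth stating explicitly:

* **Linearity on the logit scale.** Trajectories are lines in
  logit space, hence approximately linear on the score scale away from
  the bounds. This is a short-horizon assumption — reasonable for the
  6-to-24-month windows of a trial, not for a lifetime course.
* **One shared precision.** The likelihood allows a per-observation
  $\nu_{ij}$, but with roughly five visits per patient a richer
  structure is not identifiable; we fit a single $\nu$ per
  endpoint/stratum (an extension point exists in the likelihood code).
* **Random effects.** $(\alpha_i, \beta_i)$ are bivariate normal with
  unstructured covariance (standard deviations $\sigma_\alpha,
  \sigma_\beta$, correlation $\rho$). The distributional family and the
  presence of a correlation are modelling choices; we keep the
  correlation free rather than forcing independence.

Scores exactly at a bound are compressed into the open interval with
$(y(N-1)+0.5)/N$, $N$ the number of observations — the usual device for
beta likelihoods, displacing a boundary value by half an observation's
mass ($0.5/N$); interior values are untouched so the transform is exactly
linear and invertible away from the bounds.

### Priors and MCMC

"Diffuse and non-informative" is made concrete in `prior_spec()`:
Normal(0, 10²) on the population intercept and slope (logit scale),
half-Cauchy(5) on both random-effect standard deviations, Uniform(−1, 1)
on the correlation, and Normal(0, 5²) on $\log\nu$. All are configurable.
With 59 patients these priors are dominated by the data for every
parameter except $\sigma_\beta$, whose posterior is prior-influenced when
slopes are nearly homogeneous — visible as slower mixing for that
parameter.

`fit_mcmc()` runs JAGS (Gibbs/Metropolis) with per-chain RNGs seeded
from a single seed, so identical calls give bitwise-identical draws.
Convergence is flagged (not silently ignored) when any split-Rhat
exceeds 1.05 or the population-parameter effective sample size falls
below 400; the defaults of 2 chains × 2000 kept iterations (500
adaptation, 500 burn-in) are adequate for the population parameters, and
the flag tells you when they are not. `posterior_fit_check()` overlays
posterior-mean trajectories and predictive intervals on the data and
reports the fraction of observations covered.

## The synthetic cohort

The study's NHS data are available only on request, so
`simulate_cohort()` generates cohorts with the study's *structure*: 44
*MTM1* and 15 *DNM2* patients; baseline-age strata 0–2 / 2–6 / 6–16 /
>16 with the published per-genotype counts (12/10/13/9 and 0/1/1/13) and
sex ratios; visit schedules that follow the patient's age (3-monthly
under 2 years, 6-monthly from 2–6, months 6 and 12 then yearly above 6,
switching regime as the patient ages); follow-up drawn uniformly from
12–48 months (some patients were followed one year, some four); baseline
ages uniform within stratum, with 45 years as the adult cap.

The generating parameters are **invented plausible values** — the source
study prints no parameter estimates — chosen once: population intercept
0.2 and slope −0.002/month on the logit scale (near-stability with slow
decline), random-effect SDs 0.8 (patients spread over much of the score
range) and 0.01/month, correlation 0, and $\nu = 60$ (a few points of
visit-to-visit noise on a 0–100 scale). Everything downstream treats
them as unknowns to be recovered.

What the synthetic cohort does *not* emulate: mortality, drop-out,
hospitalisation shocks, placebo effects, measurement-error structure
beyond the beta likelihood, or any real-data departure from
logit-linearity. Passing tests on synthetic cohorts therefore establish
that the machinery is correct *under the model's own assumptions*; they
cannot certify the model against real CNM data.

## Individual prediction

`predict_individual()` simulates futures for a fitted patient from each
posterior draw's $(\alpha_i, \beta_i, \nu)$ — parameter uncertainty plus
beta noise. Only pre-treatment data enter the fit, so no post-treatment
observation can influence its own reference distribution.

Trial enrolees with only a run-in period have no posterior of their own.
`predict_run_in()` draws a candidate effect pair from each posterior
draw's population distribution and importance-reweights the candidates
by the beta likelihood of the run-in observations — a one-pass
approximation to the exact posterior that borrows population information
exactly as intended. Two guards: the importance effective sample size
$(\sum w)^2/\sum w^2$ triggers a warning below 200 (the approximation is
then resting on too few candidates), and `refit = TRUE` provides the
exact alternative of re-running the MCMC with the run-in patient
included. With zero random-effect variance all weights are equal and the
run-in predictive collapses to the population-marginal predictive
(`predict_population()`), which is also the explicit no-data option.

Interval width behaviour under the synthetic defaults deserves a note:
with $\nu = 60$, observation noise dominates individual parameter
uncertainty, so a run-in patient's 6-month interval is only slightly
wider than a long-follow-up patient's — and the longer extrapolation of
the long-follow-up patient from their data centroid can even reverse the
comparison in individual replicates. The robust orderings, which the
test suite asserts, are: population-marginal predictive ⊇ any
data-conditioned predictive, and interval width non-increasing in run-in
length. Proximity to the score bounds narrows intervals automatically
through the beta variance; no correction is applied.

## The responder rule and its null behaviour

`joint_improvement_probability()` estimates, by Monte Carlo over ≥4000
trajectories, the orthant probability that an untreated trajectory is at
least as good as the observed post-treatment values at **all** visits
simultaneously (componentwise ≥ for increasing endpoints, ≤ for
decreasing; ties inclusive, immaterial for continuous draws). A patient
is a responder when this probability is ≤ 0.01 (inclusive). Clinical
relevance — e.g. an 8-point FEV1 gain, the annual decline rate of
teenage Duchenne patients used as a reference — is a separate flag, not
part of the responder definition.

The statistic's null distribution matters for design. Evaluated at
futures drawn from the predictive itself, the joint survival function is
*not* uniform: for $k$ conditionally independent visits it is a product
of $k$ uniforms, so

$$P(\text{joint } p \le q) \;=\; P\!\big(\Gamma(k,1) \ge -\ln q\big)
  \;=\; 0.162 \ \text{ for } k = 3,\ q = 0.01,$$

far above $q$. Dependence across visits (shared posterior uncertainty)
pulls this down toward $q$ — reaching it only in the comonotone limit —
and under the defaults the measured per-patient null responder rate is
about 0.09–0.11 (`estimate_null_responder_rate()`;
`null_responder_rate()` gives the analytic independence value). This is
a property of the rule itself, independent of the endpoint. The
per-patient rule is therefore *anti-conservative on its own*; Type I
control comes entirely from the trial-level calibration below, which is
why the calibration must be run against the rule's measured null rate
rather than the nominal cut-off.

## Trial-level calibration and assurance

A trial with $n$ patients counts responders; with a uniform Beta(1, 1)
prior the response-rate posterior after $k$ responders is
Beta(1 + k, 1 + n − k). The decision statistic is the posterior
probability that this rate exceeds the null rate, with the null-rate
reference distribution fitted by moments (a beta) to the response rates
of simulated null trials — a degenerate point-mass alternative is also
provided. The trial succeeds when the statistic exceeds a threshold $c$;
`calibrate_threshold()` picks the smallest $c$ on a 0.01 grid (matching
a percent-scale threshold; ties resolved upward, i.e. conservatively)
whose estimated null rejection rate is ≤ 5%.

Null trials come in two modes: the *full* mode pushes every simulated
patient through the entire pipeline (history → importance predictive →
joint probability → responder call), while the default *shortcut* mode
draws responder indicators as Bernoulli with the rule's measured null
rate — the two agree because responder calls are independent across
patients given the rate. A fast exact route (numerical integration of
the beta densities) backs the Monte-Carlo calibration and is checked
against exhaustive binomial enumeration in the tests.

`assurance_curve()` reports, for each responder-rate increase $\Delta$,
the probability that the calibrated rule declares success when each
patient responds with probability (null rate + $\Delta$) — the Bayesian
assurance or expected power. Curves are computed for n = 12 and 24, each
with its **own** calibrated threshold, so the curve's value at
$\Delta = 0$ is exactly that design's Type I estimate (the zero-effect
grid point reuses the calibration trials to make the identity exact).
Assurance depends on the endpoint only through the responder
probabilities, so one curve serves all endpoints pooled into a single
responder count.

## Numerical choices and degenerate inputs

* Joint probabilities and rate-difference probabilities carry a binomial
  Monte-Carlo standard error attribute; defaults (≥4000 trajectories,
  10⁵ rate draws) keep those errors well below the decision tolerances.
* The exact integration route uses `integrate()` with relative tolerance
  1e−10; the moment fit of the null-rate beta refuses impossible moment
  pairs rather than returning nonsense shapes.
* A dataset with a single patient and two visits fits without error and
  returns prior-wide random-effect posteriors; empty future-time vectors
  give empty (zero-column) predictives; a zero follow-up gives the
  single baseline visit.
* All randomness flows from explicit integer seeds; every simulation
  object records the seed it was built from.

## Problem sizes

The test suite and the acceptance script use sizes chosen to make
Monte-Carlo error small relative to the tolerances they assert:
10,000 simulated patients (4000 predictive draws each) for the null
responder rate, 10,000 + 10,000 null trials for calibration and fresh
Type I estimation, 5,000 held-out patients for interval coverage, and 20
replicate 59-patient cohorts with 2 chains × 1000 kept iterations for
parameter recovery. Unit tests run reduced versions of the same
computations.

## Known limitations

* The model is linear on the logit scale; real long-horizon trajectories
  need not be, and predictions degrade with the prediction horizon.
* Importance reweighting for run-in patients can collapse for long or
  surprising run-ins (low effective sample size); the exact refit path
  is the fallback.
* The per-patient responder rule is anti-conservative under the null by
  construction; any use of the rule outside the calibrated trial-level
  decision must account for its true null rate.
* Placebo effects, informative drop-out and rare acute events
  (hospitalisations) are outside the model; a placebo effect would enter
  as an intercept step and slope change at treatment onset
  (`treatment_effect()` parameterises exactly this for sensitivity
  simulations: the shift applies from onset, with the slope change
  accruing per month since onset — the continuous-in-time reading of a
  treatment that changes level and slope).
* The synthetic generating parameters are plausible inventions; nothing
  anchors them to the real cohort, and conclusions from synthetic
  experiments are about the method, not about centronuclear myopathy.
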