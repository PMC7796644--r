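---
title: "Time-varying cumulative-exposure models for maintenance trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying cumulative-exposure models for maintenance trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Maintenance trials randomize patients to continue or stop a targeted
therapy (here, an anti-VEGF antibody given as 5 mg/kg "cures" every two
weeks) during the chemotherapy-free intervals (CFIs) that punctuate
treatment of metastatic colorectal cancer. An intention-to-treat (ITT)
analysis compares arms as randomized, but over a follow-up of several
years actual exposure drifts far from the randomized assignment:
patients skip cures, reduce doses, discontinue for toxicity or by
investigator decision, and both arms receive the drug again during
re-treatment sequences. A time-invariant arm indicator then mixes the
prognosis of patients who never took the drug with that of heavily
exposed patients.

This package implements a re-analysis strategy for such trials: replace
the arm indicator with time-varying cumulative-exposure metrics inside a
counting-process Cox model, compare the fits by AIC, and let the data
estimate how the effect of a dose decays with time since intake.

## The five exposure metrics

Let $X_i(t_k)$ be the dose (in cure units) received by patient $i$ at
time $t_k$. All metrics use only doses strictly before the evaluation
time $t$:

* **CE** (updated cumulative dose): $CE_i(t) = \sum_{t_k < t} X_i(t_k)$.
* **CEQ** (quantile categories): the risk set's non-zero $CE_i(t)$ values
  are cut at their tertiles (five categories, with the control arm as
  reference and a separate class for maintenance patients with no dose
  yet) or quartiles (four categories). Cutpoints are recomputed at every
  evaluation time.
* **StCE** (risk-set standardization): $CE_i(t)$ converted to a z-score
  over the patients at risk at $t$, removing the mechanical growth of
  cumulative dose over follow-up.
* **TBC** (theoretical blood concentration): one-compartment exponential
  decay, $TBC_i(t) = \sum_{t_k < t} X_i(t_k)\, 0.5^{(t - t_k)/h}$ with
  half-life $h = 20$ days from published pharmacokinetics.
* **WCE** (weighted cumulative exposure):
  $WCE_i(t) = \sum_{t_k < t} X_i(t_k)\, w(t - t_k)$, with $w$ an
  unpenalized cubic B-spline on $[0, W]$ estimated from the data through
  artificial covariates $D_{ij}(t) = \sum_k X_i(t_k) B_j(t - t_k)$.

Each metric enters a multivariable Cox model alongside fixed baseline
covariates (age group, sex, primary-tumor resection, alkaline
phosphatase, tumor site) and carried-forward time-varying covariates
(WHO performance status, a toxicity indicator, weight, hemoglobin,
bilirubin, blood pressure). Two exposure scopes are supported: CFI-only
exposure and overall exposure including induction.

## Conventions that matter

**Strict past.** A dose administered exactly at $t$ influences the hazard
only at strictly later times. This removes same-instant reverse
causation (a patient cannot be protected at the instant of a cure
administered because they were well enough to receive it) and fixes all
boundary cases: a dose at an interval boundary belongs to the later
interval.

**Decay direction.** The concentration metric is implemented as
$0.5^{(t - t_k)/h}$, a weight that shrinks as a dose ages — the
one-compartment elimination model. (Printed formulas sometimes carry the
exponent with the opposite sign, which would make past doses grow.)

**Evaluation at risk-set times.** The partial likelihood reads covariates
only at event times. The counting-process builder cuts every patient's
follow-up at all cohort event times (plus the patient's own dose and
covariate-update times, under the default policy), and exposure columns
are evaluated at each row's *stop* time. The stop of the row covering an
event is the event time itself, so decaying metrics are exact where the
likelihood looks; evaluating at interval starts would under-decay the
concentration by up to one inter-event gap.

**Risk-set statistics.** StCE uses the sample (n − 1) standard deviation
over the patients at risk; a zero-variance risk set maps to all-zero
scores. CEQ cutpoints are type-7 quantiles of the non-zero values in the
risk set, ties going to the lower category; fewer distinct non-zero
values than categories is reported as a degenerate-risk-set error and,
inside the model suite, recorded as that model's failure rather than
aborting the run. Under the quartile scheme a zero cumulative dose (rare
with overall scope) is assigned to the lowest category.

**CFI scope.** CFI exposure means doses received during chemotherapy-free
intervals. When the data carry a per-dose `during_cfi` flag (the
generator writes one) it is used directly, so cures of a CFI that began
before the analysis landmark count; without the flag the package falls
back to treating all pre-landmark doses as induction. The fallback makes
the CFI-scope dose identically zero just after the landmark, which can
degenerate the early tertile risk sets — one reason the flag semantics
are preferred when available.

**Ties and landmarking.** Efron's approximation is the default ties
method (configurable to Breslow). The analysis baseline is shifted to
182 days ("6 months") after randomization — the expected start of the
first CFI — and patients who died, progressed, were lost, or had missing
required covariates before then are excluded with per-category counts. A
censoring tied with an event keeps the censored patient in the risk set
at that time.

## The weight function and its estimation

The spline basis is clamped cubic on $[0, W]$ with 1–3 interior knots,
placed at quantiles of the observed dose lags (equally spaced as a
fallback when exposure information is too thin). The unconstrained basis
with $k$ interior knots has $k + 4$ functions; the constrained variant
drops the two rightmost, forcing $w(W) = 0$ with a flat approach — the
assumption that effects vanish smoothly at the window edge. Both
variants are available because the original analysis does not state
which was used; in our simulations the constrained fit is markedly more
stable at long lags, where unpenalized splines otherwise oscillate
around zero.

The window $W$ is chosen by AIC among 120, 365 and 730 days (ties go to
the smaller window; candidates that fail to converge are excluded with a
warning). Windows are compared at a *common, parsimonious* spline
specification — one interior knot, right end constrained to zero — and
the knot count is re-selected by AIC only at the chosen window. Both
choices matter in practice: an unconstrained basis estimates a free
weight at each candidate's own right end, and per-window knot
re-optimization gives each candidate its own model-selection optimism,
so under either the AIC difference stops reflecting the window itself.
The constraint is also the very hypothesis a window encodes (no effect
at and beyond the edge). Even so, window discrimination is intrinsically
weak when doses recur on a rigid biweekly rhythm: the observable
contrast is mostly "recently dosed versus not", which any decaying
weight reproduces at any window; discrimination improves when the true
effect is concentrated on a scale much smaller than the larger windows'
knot spacing. The fitted weight gets a pointwise 95% band by the delta
method, $\mathrm{var}(\hat w(u)) = b(u)^\top \hat\Sigma_\theta b(u)$, and
hazard-ratio curves for hypothetical dosing patterns are
$\exp\{\sum_k X(t_k)\, \hat w(t - t_k)\}$ against a no-dose reference.
For the fixed-decay model, pattern hazard ratios are the unit hazard
ratio raised to the concentration.

## Proportional-hazards diagnostics

The global test is the classical scaled-Schoenfeld-residual statistic:
with $r_k$ the Schoenfeld residual vector at the $k$-th of $d$ events,
$g$ a transform of event time, and $V$ the coefficient covariance,

$$T = \frac{d \; u^\top V u}{\sum_k (g_k - \bar g)^2}, \qquad
  u = \sum_k (g_k - \bar g) r_k,$$

is compared to $\chi^2$ with one degree of freedom per coefficient. The
default transform is the left-continuous Kaplan–Meier scale
$g(t) = 1 - \widehat{KM}(t^-)$; identity and rank transforms are
available. We implement the statistic directly (rather than delegating)
so that it has a closed, testable form; the test suite checks it to
$10^{-6}$ against an independent from-scratch computation of the
residuals, the Kaplan–Meier transform and the quadratic form, and checks
its type-I error calibration on null simulations. Current versions of
general-purpose survival software compute a related but different exact
score test, so small numerical differences from `survival::cox.zph` are
expected; conclusions agree.

## What the generator emulates — and what it does not

`sim_config()` encodes the trial structure: 488 patients (the analysis
then keeps those alive and progression-free at 6 months), 1:1 arms, 12
biweekly induction cures in both arms, alternating CFIs and 8-cure
re-treatment sequences, 8-weekly covariate assessments, administrative
censoring at 5 years. Where the source trial reports a quantity we use
it as the default: discontinuation-reason mix 28.7% / 8.3% / 11.3%
(investigator / toxicity / other), baseline marginals (about a third
women, half under 65, 18% elevated alkaline phosphatase), and a baseline
hazard calibrated so that roughly 84% die during follow-up with a median
of about 16 months from the landmark — a soft calibration, not a fitted
quantity.

Quantities the trial does not report are set once to field-plausible
values and documented here rather than tuned: CFI lengths are log-normal
with median 120 days; per-cure adherence during CFIs is 0.8; scheduled
induction/re-treatment cures are received with probability 0.97; 25% of
induction sequences stop early (8–11 cycles); per-patient dose intensity
is 1 / 0.75 / 0.5 with probabilities 0.75 / 0.15 / 0.10 and a log-normal
8% per-cure jitter (weight-based dosing makes received doses
continuous — without this, cumulative doses take too few distinct values
for risk-set quantiles to exist, something real mg/kg dosing never
suffers from); cycle delays are half-normal with 1.5-day scale;
continuous covariates follow bounded random walks and performance status
a worsening-biased Markov chain. An optional knob ties CFI adherence to
baseline performance status, to emulate confounding by indication;
it is off by default, so the default cohorts are well-specified for
effect-recovery experiments.

Death times come from exact inversion of a piecewise-constant daily
hazard $h_0(t)\exp\{\beta \cdot \text{Exposure}_i(t) + \gamma^\top
Z_i(t)\}$ with the exposure evaluated at mid-day and the event time
interpolated within the day (so event times are continuous and ties are
negligible). The truth — per-day exposure and linear predictor — is kept
in a segregated `truth` element and recomputed through the same exposure
functions the estimators use.

The generator does not model tumor progression as an endpoint, competing
risks, multi-compartment pharmacokinetics, center effects, or informative
censoring. Passing recovery tests on these cohorts therefore shows that
the estimators are correct under a faithful protocol structure, not that
the original trial's data-generating process is captured.

## Numerical choices and problem sizes

Newton–Raphson fitting of the partial likelihood is delegated to the
`survival` package (Efron ties by default); an explicit grid-search
oracle on hand-written partial likelihoods guards the wrapper. Cut
points closer than $10^{-4}$ days are merged when building the
counting-process table (event-time cuts taking priority): simulated
event times are continuous, and a sub-second gap both carries no
information and falls inside the tie tolerance of the survival
routines, which would otherwise see zero-length intervals. Spline
evaluation uses `splines::splineDesign` on a clamped knot vector;
degenerate designs (covariates without variation, inestimable
coefficients) are errors, and possible monotone likelihoods are
surfaced as warnings rather than silent results.

The simulation experiments in the test suite use sizes chosen to give
stable Monte-Carlo summaries at desk scale: 20 replicates of 500-patient
cohorts for effect recovery, confidence-interval coverage and AIC model
ordering; 20 replicates for exposure-window selection; 100 null
replicates of 200-patient cohorts for the proportional-hazards type-I
error; 350-patient cohorts with randomized dose timings (the validation
design of the weighted-cumulative-exposure literature — a rigid biweekly
protocol carries much less lag information) for weight-shape recovery.
The acceptance script repeats the same experiments with 10 / 8 / 60
replicates respectively to keep a single run short; its summaries are
therefore slightly noisier than the test suite's.

## Known limitations

* Unpenalized spline weights oscillate at lags where exposure
  information is thin; use the constrained basis or fewer knots for
  stable tails. Penalized estimation is out of scope.
* At moderate effect sizes a one-parameter decaying metric captures
  nearly all of the cumulative-exposure signal, so the spline model's
  AIC advantage over the unweighted cumulative dose can be marginal:
  the shape refinement it adds is small relative to its extra degrees
  of freedom. (The same degrees-of-freedom accounting explains why a
  flexible weight model can trail a fixed-decay model on AIC while
  matching its deviance.)
* The risk-set quantile metric is undefined early in follow-up when too
  few patients have distinct non-zero cumulative doses; the suite
  records this per model instead of failing the run.
* Left truncation beyond the landmark construction, time-varying
  coefficients (non-proportional hazards modeling) and frailty terms are
  not implemented.
* With the fallback scope rule (no `during_cfi` flag), CFI-scope
  estimates exclude early-CFI cures received before the landmark and
  include re-treatment cures after it; flag semantics are preferred.
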