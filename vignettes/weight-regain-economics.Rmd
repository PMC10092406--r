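---
title: "From weight-regain trajectories to cost-effectiveness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From weight-regain trajectories to cost-effectiveness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weightregain)
library(dplyr)
```

## The problem

Behavioural weight management programmes (BWMPs) — diet and physical-activity
interventions for adults with obesity — reliably produce weight loss relative
to control while contact is intensive, but the advantage erodes after the
programme ends. Whether such programmes are worth paying for therefore hinges
on the *trajectory* of that erosion: a 2.8 kg advantage that persists for a
decade buys far more health than one that vanishes in two years. This package
implements the full analytic chain for that question:

1. **Corpus construction** — study-level extraction tables (one row per arm
   per visit) are turned into intervention-minus-control *difference series*
   with the clock re-zeroed at programme end.
2. **Regain synthesis** — three complementary models estimate how fast the
   difference closes, plus a quality-of-life (QoL) co-analysis.
3. **Scenario trajectory** — a piecewise-linear weight-difference function
   `D(t)` feeds the economic model.
4. **Proportional multi-state lifetable** — BMI shifts reduce disease
   incidence via population impact fractions; two simulated populations yield
   discounted QALYs and costs.
5. **Economics and uncertainty** — maximum cost-effective price
   `C(lambda) = lambda * Q + K`, return on investment, Monte Carlo 95%
   uncertainty intervals, and tornado decomposition.

## Difference series

For each study, the control arm's mean weight change from baseline is
subtracted from the intervention arm's at every visit where the two arms can
be matched in time. Visits are matched within ±0.5 month, because extraction
tables report visit schedules at study level and minor rounding is common.
Studies with several intervention arms are pooled by an n-weighted average of
the arms (the alternative of keeping the most intensive arm is available via
`combine = "most_intensive"`); the field reports per-study effects but rarely
states the pooling rule, so both options are explicit. The sampling variance
of a difference is `sd_i^2/n_i + sd_c^2/n_c` when arm SDs are available and
missing otherwise, in which case downstream fitters weight by total analyzed
n instead.

Weight changes are negative for loss throughout; time is in months
everywhere, converted to years only for reporting. QoL scales are
sign-normalised (higher = better) at the point where standardized mean
differences are formed rather than at load time, so that a corpus written
back to CSV reproduces its source field-for-field.

Eligibility for regain synthesis mirrors the design of the underlying
evidence base: a study contributes only if the intervention had actually
lost weight relative to control at programme end (difference < 0 at t = 0),
has at least one post-programme observation, and followed participants for
at least 12 months from baseline.

## The three synthesis models

**Model "mixed"** regresses all post-programme differences on months since
programme end with a common slope and a random intercept per study,
estimated by REML through `lme4`. Observations are inverse-variance weighted
when at least 80% of points carry variances (dot sizes in the field's
standard forest-style figures imply such weighting), otherwise by total n.
With a single study the random intercept is unidentifiable and the model
collapses, exactly, to ordinary least squares. When the data interpolate
`a_j + b t` with zero residual (as synthetic noiseless corpora do), profiled
REML is ill-posed — the residual variance estimate collapses and the
optimiser returns an arbitrary between-study variance — so that degenerate
case is detected and solved in closed form: common slope by differencing,
intercepts exactly, `tau^2 = Var(a_j)`.

**Model "metareg"** reduces each study to its final post-programme
difference and fits a random-effects meta-regression of that difference on
final follow-up time (`metafor`, REML `tau^2`, weights `1/(v_i + tau^2)`).
Because it discards the interior visits, it is typically flatter than the
mixed model when later follow-ups are sparse. Fewer than three studies, or
no variation in final follow-up, are explicit errors rather than silent
degeneracies.

**The time-to-event model** records, per study, the first time the
difference reaches zero, linearly interpolated between the bracketing
visits; series still negative at their last visit are censored there.
Interpolated rather than visit-snapped times are used because visit grids
are coarse (6–12 months) and snapping would bias the survival curve upward.
The Kaplan–Meier product-limit estimator (via `survival`) treats each study
as one unit; the median is the first time survival reaches 0.5 and is
reported as undefined when the curve never gets there — which genuinely
happens when high-risk-of-bias studies are removed.

The QoL co-analysis forms standardized mean differences with the pooled
change-score SD (no small-sample correction by default; Hedges' correction
is behind a flag, since change-score meta-analyses in this area convention-
ally report uncorrected SMDs), back-converts to SF-36 points via per-study
SF-36 SDs (median and IQR across studies), and estimates the weight–QoL
association by regressing QoL SMDs on paired weight differences with the
same random-intercept machinery.

The publication-bias check regresses programme-end differences on maximum
follow-up length across studies. It is fitted as a random-effects
meta-regression with the Knapp–Hartung adjustment: a fixed-weight regression
with normal-theory intervals ignores between-study heterogeneity and
undercovers at realistic corpus sizes, while the heterogeneity-aware
interval holds its nominal 95% level (checked by simulation in the test
suite).

## Scenario trajectory

`make_trajectory(d0, rate)` defines `D(t) = min(d0 + rate * t, 0)`: linear
regain from the programme-end difference `d0 < 0` until the advantage is
gone at `t_zero = -d0/rate` months, zero afterwards. A `no_regain` mode
holds `d0` forever — the optimistic assumption some decision models still
make, retained here as a comparator. During the programme itself the
difference ramps linearly from 0 at baseline to `d0` at programme end
(evidence tables rarely resolve the within-programme shape; this affects
only the first annual cycle). The default programme length is 6.5 months, a
typical intensive-phase duration for these programmes.

BMI shifts are the static conversion `dBMI = D(t)/height^2` with age- and
sex-specific heights. Dynamic energy-balance modelling is deliberately not
used: the regain trajectory is *observed*, so the dynamics that such models
would predict are already folded into `D(t)`; re-applying them would double
count. This is a documented simplification.

## The lifetable engine

Every 2017 age–sex cohort (single year of age 18–100, both sexes) is aged
to 100 in annual cycles under two scenarios. Disease processes are
three-state models per disease and stratum — susceptible `S`, prevalent
case `C`, dead of the disease — with annual Euler steps:

```
C(y+1) = C(y) + i' S(y) - f C(y),   i' = i (1 - PIF(y))
```

The reference scenario has `PIF = 0`. The population impact fraction for a
BMI shift `delta` is computed on a 10–60 kg/m² grid (step 0.1) over the
stratum's lognormal BMI distribution, moving only the intervention-eligible
mass (BMI ≥ 30) and evaluating `RR(b) = rr_unit^max(0, b - b_ref)` with
`b_ref = 21` kg/m² by default. Because the eligible mass (≥ 30) stays above
`b_ref` for any realistic shift, the shifted integral reduces to
`exp(theta * delta)` times the unshifted one; the engine uses this exact
shortcut when the inequality holds and falls back to the full grid
otherwise, and a test verifies the first-order convergence of the grid
estimate. Diseases are treated as independent (no diabetes-to-cardio
dependency).

All-cause mortality in the intervention scenario equals reference mortality
minus the summed disease-mortality differences, so only the modelled
diseases transmit the benefit. Person-years accrue by trapezoid on
survivors; utility in a stratum-year is the baseline utility minus
prevalence-weighted disease decrements, floored at zero with a warning
(comorbidity overload); QALYs and costs are discounted to the baseline year
at 3.5%/yr (the NICE rate). Health-sector costs comprise per-prevalent-case
disease costs plus an other-cause cost per person-year — included by
default so that added life years carry their own care costs. Social-care
costs accrue above age 85 and count only under the health-and-social-care
perspective. Cohorts close at age 100; residual survivors earn no further
QALYs or costs (a truncation, biased slightly against the intervention).
Annual Euler steps are used because the published description of this model
class does not specify a finer discretisation; rates large enough to break
the step (negative states) abort with a stability diagnostic rather than
silently clamping.

Numerical identities the engine is required to satisfy, all enforced in the
test suite: a null intervention leaves the two scenarios bitwise identical;
alive plus cumulative deaths equals the initial cohort to 1e-9 in every
stratum-year; QALY gains are monotone in `|d0|` and `no_regain` dominates
`linear_regain`; cost offsets are homogeneous of degree one in unit costs;
discounting matches the closed-form annuity to 12+ digits.

## Economics

With `Q` the discounted QALY gain and `K` the discounted cost offset per
person offered (denominator: the whole eligible population, i.e. adults
with BMI ≥ 30), the maximum cost-effective price is affine,
`C(lambda) = lambda Q + K`, with `C(0) = K` the cost-saving price. Return on
investment monetises QALYs at £60 000 and is reported as *net* return per
pound, `(vQ + K - C)/C` — the gross variant is behind a flag because axis
conventions for published ROI figures vary. Benefits are assumed to scale
linearly with the programme-end weight difference, so
`scale_by_initial_loss()` rescales `Q`, `K` and every threshold price by
`w_new/w_base`.

## Uncertainty

Monte Carlo propagation (default 5000 iterations) draws: the *magnitude* of
the programme-end weight loss from a lognormal (matched to a mean and 95%
interval via `lognormal_from_mean_ci()`, which fixes the arithmetic mean
and takes the log-scale spread from the interval); multiplicative lognormal
perturbations of relative risks and unit costs; and a normal perturbation
of utility decrements. The regain *rate* is fixed across draws — start-point
uncertainty dominates because that is where the evidence is concentrated.
Intervals are percentile-based, not normal-approximation, because the price
outputs are strongly right-skewed (the lognormal weight-loss input enters
multiplicatively). Each input group owns an RNG stream split
deterministically from the master seed, so adding a group never perturbs
the draws of the others, and a fixed seed reproduces results bitwise.
Out-of-bounds draws (e.g. negative decrement multipliers) are redrawn and
counted. The tornado decomposition evaluates the pipeline at each group's
2.5th/97.5th percentile with the others held central and ranks groups by
induced spread.

The default weight-loss interval (mean 2.8 kg, 95% interval 1.2–4.4 kg)
reflects the between-study spread implied by an intercept SD of 0.8 kg; the
relative-risk and cost multipliers (0.7–1.43) and utility multiplier
(0.9–1.1) are conventional magnitudes for this model class. These are
scenario defaults, not estimates.

## What the synthetic generators do and do not emulate

`generate_corpus()` reproduces the *statistical structure* the synthesis
assumes: per-study programme-end differences `a_j ~ N(-2.8, 0.8^2)` kg, a
common linear regain slope (0.027 kg/month by default), observation noise
of 0.5 kg, irregular follow-up at programme end + {6, 12, 24, 36, 60}
months with progressive dropout, arm sizes of 30–150, a risk-of-bias mix of
23/53/24% (low/unclear/high), and QoL on ~25% of studies with a built-in
slope of -0.02 SMD per kg of weight difference. The QoL series is generated
as `SMD = 0.21 + slope * (D - mean_d0) + noise`, anchoring the intercepts
independently of each study's own weight level so the built-in slope is
identifiable — anchoring at the study's own intercept would correlate the
random intercepts with the regressor and no estimator could recover the
slope. The generator does *not* emulate: non-linear regain shapes,
informative dropout, correlated multi-arm designs, or reporting biases.
Passing parameter-recovery tests therefore demonstrates correctness of the
estimators under the assumed data-generating process, not robustness to its
violations.

`generate_epi()` is a toy: Gompertz mortality, lognormal BMI with ~25%
obesity prevalence, four diseases (IHD, stroke, type 2 diabetes, colorectal
cancer) with relative risks per BMI unit between 1.02 and 1.15, plausible
utilities and unit costs. It is deliberately *not* calibrated to UK
statistics, so absolute economic outputs from it are illustrative; the
engine's correctness is established by its structural identities, and real
analyses should supply their own `epi_inputs()`.

## Problem sizes and determinism

The test suite uses 200 replicates for slope-recovery (bias < 10% of
truth), 500 null seeds for bias-check coverage (≥ 93%), and one
5000-iteration Monte Carlo run of the full toy pipeline; these sizes give
stable Monte Carlo error on the quantities asserted while keeping a default
`R CMD check`-style run comfortably interactive. All stochastic tests fix
their seeds.

## Known limitations

- Baseline disease prevalence starts at zero for every cohort; with
  age-increasing incidence this understates prevalence at older entry ages
  in both scenarios (it differences out to first order, but not exactly).
- The reference scenario is static baseline epidemiology: no secular trends
  in obesity, incidence or costs.
- Disease independence; remission is not modelled.
- The eligibility cut (BMI ≥ 30) interacts with a population-level PIF: the
  weight difference is applied to all eligible individuals uniformly, not
  scaled by baseline weight.
- The economic engine's absolute outputs are only as good as the
  epidemiological inputs supplied; the bundled generator is a labelled toy.

## A minimal run

```{r example, eval = FALSE}
corpus <- generate_corpus(corpus_params(n_studies = 50, seed = 7))
series <- corpus |> build_difference_series() |>
  filter_regain_eligible(corpus)
fit <- fit_mixed(series)
traj <- make_trajectory(fit$intercept, fit$slope)
epi <- generate_epi(seed = 3)
econ <- econ_summary(run_lifetable(epi, traj, trace = FALSE))
mc <- run_mc(build_econ_pipeline(epi, rate = fit$slope),
             econ_uncertainty_groups(), n_iterations = 5000, seed = 42)
tidy(mc)
```
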