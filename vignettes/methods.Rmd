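---
title: "Methods: bimodal respirometry, breathing synchrony and mixed-model inference in airsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bimodal respirometry, breathing synchrony and mixed-model inference in airsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airsync)
```

## The problem

Air-breathing fishes meet part of their oxygen demand by surfacing and
gulping air, a behaviour that trades oxygen acquisition against exposure to
surface predators. In social species the behaviour is partly collective:
fish surface in temporal clusters, and surfacing by one individual can be
triggered by breaths or aggressive interactions of others. `airsync`
implements the complete computational pipeline for studying this system in
groups of four fish observed across an aquatic oxygen ladder (100, 80, 60,
40, 20% air saturation, plus a recovery observation), with each fish also
characterised physiologically by bimodal respirometry. Every stage can be
exercised end to end on a synthetic-data generator with known ground truth,
so the pipeline's recovery properties are testable without any external
data.

## Bimodal respirometry

Each fish sits in a sealed chamber of total volume 2.5 L holding an air
phase of roughly 200 mL above the water. An intermittent stopped-flow cycle
of 900 s alternates a 600-s closed period, during which oxygen declines in
both phases, with a 300-s flush. Over a 17-hr record this yields 68
measurement cycles.

**Air-phase volume calibration.** The exact air volume is obtained by
injecting a bolus of pure N2 into the sealed air space. Under well-mixed,
isobaric venting the O2 partial pressure dilutes as
$F_1 = F_0\,V/(V+V_b)$, inverted by `calibrate_air_volume()` as
$V = V_b\,F_1/(F_0-F_1)$. A plug-flow alternative was rejected as
physically implausible for a stirred chamber. Replicate boluses are
averaged.

**Per-cycle uptake.** Within each closed period (minus the first
`settle_skip` seconds, default 60 s, discarded as a mixing artefact — the
instrument literature shows a settling transient but no standard value, so
the default is configurable) an ordinary least-squares slope is fitted per
phase. Slopes convert to mass-specific uptake as

$$\dot M_{O_2,air} = \frac{-b_{air}\,V_{air}}{R\,T\,M}, \qquad
  \dot M_{O_2,water} = \frac{-b_{water}}{100}\,\beta\,\frac{V_{water}}{M},$$

with $b_{air}$ in kPa/hr, $b_{water}$ in % air saturation/hr, $R$ the gas
constant in L kPa mmol^-1^ K^-1^, $M$ the fish mass in kg and $\beta$ the
O2 solubility of air-equilibrated fresh water (Garcia-Gordon fit at
salinity 0, ~0.25 mmol/L at 26.5 °C, with a barometric/vapour-pressure
correction). The effective water volume subtracts both the air phase and
the fish's body volume at an assumed density of 1.0 kg/L; the subtraction
is flagged in the output metadata because reasonable analysts differ on it.
Routine metabolic rate per cycle is exactly the sum of the two phases, and
the percentage of uptake obtained from air (%MO2AIR) is aggregated over
all cycles, not averaged per cycle.

**Standard metabolic rate.** SMR is the q = 0.12 quantile of the per-cycle
RMR series, on the premise that temporal variability and measurement error
push a fraction of routine measures below true SMR. Quantiles interpolate
linearly between order statistics (the default convention of common
statistical software); the interpolation rule is recorded in the output
because the quantile-method literature cites the method without fixing it.
No r² rejection filter is applied by default (none was used in the design
this replicates); an optional threshold drops and counts offending cycles.

**Units.** The internal canonical units are kPa for the air phase and %
air saturation for the water phase; `kpa_to_pct_sat()` and
`pct_sat_to_kpa()` are explicit, tested converters applied automatically
when a log arrives in the other unit.

## Behavioural event streams

A trial is 900 s of time-stamped events from a closed ethogram — breath,
attack (with target), push (with target), avoid — plus per-fish total
distance moved.

**Synchrony.** The coefficient of dispersion (CD) is the variance-to-mean
ratio of event counts across 30-s bins anchored at trial start. Thirty
seconds captures chains of surfacing spread over tens of seconds with only
a few seconds between individual fish; the bin width is exposed as a
parameter. The sample variance (n−1) is used — the source convention is
ambiguous, so the choice is recorded in the result object. A stream with
no events has an undefined CD (`NA` with a warning), never zero. For a
homogeneous Poisson stream E[CD] = 1; values above 1 indicate temporal
clumping.

**Proximity attribution.** For each breath by fish *f*, the breath is
attributed to a category when at least one qualifying reference event
occurred in the half-open window (0, 5] s before it: a breath by another
fish, an attack by *f*, an attack targeting *f*, an avoid by *f*, or any
agonistic interaction involving *f*. Lag zero does not count (simultaneous
events are not "after"), the window endpoint does, and a breath preceded by
several qualifying events still counts once — fractions are per breath, not
per pair. Avoids involve only the avoider, because targets of avoids are
not coded. `trigger_attribution()` gives the converse, per-attack view —
the fraction of attacks followed within the window by a breath of the actor
or target — which is the quantity that directly identifies the generator's
trigger probability when baseline breathing is negligible.

**Dominance.** The dominant individual is the fish with most attacks summed
over its group's trials, with a deterministic tie-break (attacks, then
attacks + pushes, then lexicographic id) whose path is logged.
`group_breaths_excluding()` supports the group-level analysis that asks
whether an aggressive individual elevates the breathing of everyone else.

## Mixed-model inference

The analysis table has one row per fish × oxygen level. Count responses
(breaths, attacks) are log1p-transformed — zeros exist, so a pure log is
unavailable; the convention is recorded. Models include fish ID nested in
group as random intercepts.

**Random structure.** The full model is first fitted by REML and the
intercept-only random structure is compared by likelihood-ratio test
against a version letting the oxygen slope vary among individuals. A
five-level categorical random slope is unestimable at 44 × 5 observations
(20 covariance parameters), so the slope candidate uses numeric oxygen
(fraction of air saturation). The simpler structure is retained unless the
slope model significantly improves parsimony; equal likelihoods favour the
intercept model.

**Backward elimination.** Fixed-effect selection runs under maximum
likelihood: at each step the droppable term with the smallest
representative |t| (the largest-|t| contrast for multi-level factors, so a
term with one strong contrast is not an early candidate) is removed unless
the likelihood-ratio test says removal significantly worsens the model
(α = 0.05 — the design this replicates reports only "significant" AIC
increases, so a conventional threshold is adopted). Interactions are
considered before their main effects, and a main effect still inside an
interaction is never a candidate. The full trail (term, t, ΔAIC, LRT p,
decision) is emitted and replays deterministically. Final models are
refitted with REML for reporting. Denominator degrees of freedom use the
Satterthwaite method; the df convention affects p-value decimals, not
conclusions, and is reported rather than matched to any particular
software.

**R² and repeatability.** Marginal and conditional R² follow the
variance-ratio definitions: fixed-effect prediction variance over total,
and fixed plus random-intercept variance over total. Adjusted (consistency)
repeatability is $R = v_{id}/(v_{id}+v_{group}+v_{res})$ from a REML fit
with the adjustment covariates as fixed effects. Uncertainty comes from a
parametric bootstrap (default 1,000 resamples; the seed is mandatory and
recorded), with the percentile interval clamped so it always brackets the
point estimate. Evidence against zero individual variance uses the
likelihood-ratio test with the halved chi-square(1) p-value appropriate for
a variance component on its boundary. A dataset with one observation per
individual is reported as unidentifiable, never as a number.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions; it is not a tuning dial.

*Respirometry*: per-cycle RMR is true SMR times (1 + surcharge), where the
surcharge is lognormal and present in 75% of cycles — the remaining
quiescent cycles put the 12% quantile of the multiplier at exactly 1, which
is what makes the quantile method well calibrated here. Declines are
forward-simulated through the inverse of the analysis equations plus
Gaussian sensor noise (0.02 kPa air, 0.15 %sat water per sample, 5-s
sampling) and an exponentially decaying mixing transient confined to the
settle window.

*Behaviour*: a marked point process per trial. Attacks are Poisson per fish
(dominant rate ×5, group-level lognormal aggression multiplier echoing the
large among-group variance in aggression), each with a random target;
targets of agonism emit avoids with probability 0.6. Baseline breaths are
Poisson with rate rising 40% from normoxia to 20% saturation. After each
attack, actor and target each breathe with probability 0.4 at an
exponential lag (mean 2 s) truncated to 5 s; after each parent breath every
other fish follows with probability 0.15 at a uniform lag in (0, 5].
Truncating trigger lags at the proximity window makes the trigger
probability directly identifiable by per-attack attribution — real
physiological lags may exceed the window, and the exponential shape is a
modelling convenience; both caveats matter when reading recovery tests as
statements about real data. Follower breaths do not recursively spawn
followers, which keeps the process subcritical and the per-origin event
counts interpretable. Rates were chosen once so that summary ranges
(breaths per group-trial, CD above 1 under triggering, proximity fractions
of tens of percent) are realistic for a social air-breathing catfish; they
are documented here, not fitted to any particular dataset.

*Isolation*: a lone fish breathes at the group baseline divided by a social
facilitation factor (default 5), with the same hypoxia response.

*Trait tables*: `simulate_trait_table()` generates the Gaussian mixed-model
test bed (44 individuals in 11 groups × 5 oxygen levels; variance
components 0.3/0.1/0.6 for individual/group/residual by default; real
activity and log-attack effects of 2.1 and 1.7 with null SMR, mass and
%MO2AIR covariates) used for elimination, R² and repeatability recovery
studies.

What the generator does **not** emulate: diurnal drift in metabolic rate,
background microbial respiration, optode drift and calibration decay,
measurement gaps, unbalanced group sizes, or behavioural non-stationarity
within a trial. Passing recovery tests therefore demonstrates correctness
of the estimators under the stated stochastic model, not robustness to
every artefact of real recordings.

## Numerical choices and degenerate inputs

- Slope fits require ≥ 3 samples; constant windows return slope 0 with
  r² = 0 rather than `NA`.
- Cycles with a *rising* O2 trace beyond a tolerance are flagged, and
  uptake is floored at zero (declining O2 is positive uptake).
- Zero total uptake makes %MO2AIR undefined (error), as does an empty RMR
  series for SMR; fewer than 20 cycles warns that the quantile is unstable.
- Trailing partial CD bins are dropped with a warning; trials in the
  replicated design are exactly 900 s, so none arise there.
- Singular or non-converged mixed fits are recorded on the fit object, not
  hidden; bootstrap refits that fail are dropped and counted.
- All simulation entry points take an explicit integer seed; identical
  configuration and seed reproduce outputs byte for byte.

## Problem sizes used in the test suite

The packaged tests run the full respirometry recovery at 50 fish × 68
cycles, the CD null calibration at 10,000 Poisson streams, oracle
equivalence for proximity at 1,000 random trials, repeatability recovery
as the median of 25 datasets at the study size (a single 44-individual
dataset has a sampling SD near 0.07, so the median across datasets is the
meaningful bias check) with bootstrap coverage at 40 × 100 resamples, and
elimination retention over 300 simulated datasets (the retention
probability sits close to the 80% mark, so the larger sample keeps the
Monte-Carlo error of the estimated rate near one percentage point). These
sizes keep each
property estimate's Monte-Carlo error well inside the tolerance it is
checked against.

## Known limitations

- The elimination procedure's per-term false-retention rate for
  between-individual covariates is slightly above nominal (the ML
  likelihood-ratio test ignores the effective sample size of 44
  individuals), a property of the replicated procedure itself.
- The repeatability bootstrap is parametric; it inherits the fitted
  model's Gaussian assumptions.
- The Dryad ingestion path (`run_dryad()`) maps arbitrary column names but
  assumes one row per event and one row per fish in the two tables; it
  does not attempt to parse proprietary video-coder exports directly.
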