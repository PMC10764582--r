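---
title: "Retrieved-dropout multiple imputation for time-to-event endpoints: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieved-dropout multiple imputation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mird)
```

## The problem

Large outcome trials (the motivating case is a cardiovascular outcome
trial, CVOT, with a time-to-first-MACE endpoint) follow thousands of
subjects for years. Some subjects leave the study early with no prior
endpoint event; the standard Cox analysis censors them at dropout, which
is only unbiased if censoring is non-informative. When dropout is
plausibly related to treatment (side effects, loss of benefit), that
assumption is suspect, and regulators increasingly ask for sensitivity
analyses under missing-not-at-random (MNAR) mechanisms that still target
the treatment-policy estimand.

`mird` implements a middle-ground MNAR assumption: subjects lost to
follow-up behave like the **retrieved dropouts (RDs)** of the same
randomized arm — subjects who also discontinued randomized treatment but
stayed in the study, so their outcomes are observed. The RD subset is the
imputation basis; dropouts get multiply-imputed event/censoring times
drawn from RD-fitted conditional survival distributions, each completed
dataset is analyzed with the usual Cox proportional-hazards model, and
the `B` estimates are pooled with Rubin's rules.

## The imputation identity

For a subject censored at `c` with covariates `Z` (treatment plus
baseline covariates), the conditional law of the unobserved event time
`T` is `P(T <= t | T > c) = 1 - S(t|Z)/S(c|Z)`. Drawing `u ~ unif(0,1)`
and solving

```
S(t | Z) / S(c | Z) = u
```

for `t` produces a draw from that conditional distribution; monotonicity
of `S` guarantees `t > c`. Everything else is the choice of `S` and how
its estimation uncertainty is propagated ("proper" imputation):

* **bootstrap** — a semi-parametric Cox fit on the RD subset, refit on
  `B` with-replacement resamples; the fitted survival curve is evaluated
  on an arithmetic grid from `c` to the subject's administrative horizon
  `C` and inverted by linear interpolation between the bracketing grid
  points. A target level below `S(C)` falls outside the grid and the
  subject is censored at `C`.
* **piecewise exponential (PWE)** — proportional hazards with a
  piecewise-constant baseline hazard `lambda_u` on `[tau_{u-1}, tau_u)`;
  the inversion is closed-form on the baseline cumulative-hazard scale.
  Parameters for imputation `b` are drawn from
  `MVN(theta_hat, vcov(theta_hat))` on the `(log lambda, beta)` scale.
* **Weibull AFT** — `log T = gamma0 + Z'gamma + sigma * eps` with Gumbel
  errors (equivalently Weibull proportional hazards with shape
  `1/sigma`); closed-form inversion
  `t = (c^(1/sigma) - exp(eta/sigma) log u)^sigma`. Draws are MVN on
  `(gamma0, gamma, log sigma)`.
* **jump to reference (J2R)** — the MNAR comparator in which active-arm
  dropouts follow the placebo conditional distribution after dropout:
  invert `S(t|trt=0,X)/S(c|trt=1,X) = u`, floored at `c`. Provided in
  the Weibull flavor only, matching how the approach is used in
  practice.

A raw inverted time is finalized against the administrative horizon
(event if `t < C`, otherwise censored at `C`) and, when a vital-status
search is available, against death: the imputed event stands only if the
imputed event date does not exceed the earlier of the death date and the
data-cut, otherwise the subject is censored at `min(death_day + 1, C)`
(the same "+1" day-counting convention as `C = D - R + 1`).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `B` | 100 (analysis), 10 (simulation grids) | imputations | 100 is a modern MI default; 10 keeps 1000-replicate grids tractable and Rubin's variance is valid for any `B >= 2` |
| `grid_width_days` | 60 | days | bootstrap grid spacing; 60 and 90 are the widths explored in the reference analysis; halving the width halves the interpolation error |
| `cutpoints` | `"quartiles"` | days | PWE interior cuts at the 25/50/75% quantiles of RD **event** times (4 pieces) |
| `partial_cov` | `FALSE` | — | `TRUE` samples only the regression coefficients, holding baseline hazards at the MLE — the behavior of the widely used R implementation that exposes only a partial covariance |
| `alpha` | 0.05 | two-sided | rejection threshold on the pooled Wald statistic |

Two defaults deserve their own paragraphs.

**PWE cut points.** The reference implementation's footnote places cuts
at `quantile(A$t2e)[2:4]` — quartiles of "t2e" in the RD dataset. Read
as quartiles of *all observed times*, this is unusable in a trial with a
short enrollment window and a common data-cut: censoring times then
cluster in the final year, all three interior cuts land inside that
cluster, and the later intervals contain no events, so the hazard there
is not estimable. Read as quartiles of *event times*, every interval
contains events whenever at least four events exist. `mird` uses event-
time quartiles, shrinking the number of pieces to the event count when
fewer than four events are available; explicit numeric cut vectors are
honored as given, and an interval without events is a hard, named error.

**Full vs partial covariance.** Proper imputation wants the full
parameter uncertainty, so the default PWE fit (an exact Poisson-
likelihood fit via episode splitting) carries the complete observed-
information covariance of `(log lambda, beta)`, and positivity-
constrained components are sampled on the log scale so every draw is a
valid model without rejection steps. The `partial_cov` flag reproduces
the restricted behavior (sample `beta`, freeze `lambda`) for comparison
with results produced by the partial-covariance implementation — the
package's own simulation-calibration tests run the PWE arm in this mode,
because the reference operating characteristics were generated that way.

## Degenerate inputs and numerical choices

* Zero events in the RD subset is a hard error with guidance, not a
  silent fallback: the method's stated operating range is roughly 5-20%
  RDs in an outcome trial.
* A near-singular information matrix (covariance diagonal above `1e4`,
  e.g. two or three RD events, or complete separation in the treatment
  indicator) is refused as "not identified". In scenario grids such
  replicates are counted and reported as failures rather than
  contributing meaningless draws. In the sparsest stress scenario
  (N = 1000, 5% RDs, 30% discontinuation) roughly 16% of replicates are
  affected: with ~5 expected RD events, the chance that every event
  falls in one arm (complete separation of the treatment coefficient) is
  close to 0.19, plus ~5% with fewer than two events. In that same
  corner the surviving Weibull fits carry a large between-imputation
  variance, and the t reference with Rubin degrees of freedom makes the
  pooled test conservative — the measured type-I error there is ~0.017,
  below nominal. This is a deliberate trade: refuse or down-weight
  unidentified imputation models rather than let near-singular
  covariance draws pass through silently.
* Bootstrap resamples with zero events (or a constant covariate) are
  redrawn, at most 25 times per slot.
* The conditional survival evaluator carries its last value forward
  beyond the largest observed RD time; imputed times landing there are
  administratively censored anyway.
* Imputed times are kept at floating precision rather than rounded to
  whole days, avoiding tie artifacts in the final Cox fit (Efron tie
  handling, Breslow-type baseline — the standard defaults of major
  survival software).
* The closed-form PWE inversion maps every conditional level to exactly
  one hazard piece; levels landing exactly on a piece boundary resolve
  to the earlier piece (a set of measure zero).
* Uniform variates are drawn once per (subject, imputation) from
  subject-keyed seed substreams: adding or removing a subject never
  perturbs other subjects' draws, and different methods run with the
  same seed consume identical uniforms, so method contrasts are not
  confounded by Monte-Carlo noise.
* Rubin inference uses the t reference with the classical
  `(B-1)(1 + W/((1+1/B)B_var))^2` degrees of freedom; `B_var = 0`
  degrades gracefully to the normal reference, which also makes the
  no-missing-data case collapse *exactly* (bit for bit) to the plain
  Cox analysis.

## What the simulator emulates — and what it does not

`simulate_trial()` generates the stated world of the operating-
characteristic study: two arms 1:1, exponential event times at 2% per
person-year (placebo), uniform 1-year enrollment, fixed 5.5-year
duration with a common administrative data-cut (`C = D - R + 1` days),
study discontinuation independent of events with uniform dropout times
(an exponential option exists), and RD labels assigned at random among
non-discontinuing subjects, per arm, at the requested fraction. Under
the alternative, the active arm runs at `rate x HR` except its RDs,
which run at the attenuated `rate x HR*` for their whole follow-up (the
off-treatment dilution), and the active-arm discontinuation fraction is
shifted additively (−2% in the power study). A Weibull event-time
option (shape configurable, scale calibrated to match the exponential
cumulative hazard at the full study duration) supports distributional
robustness checks.

Each generation stage (enrollment, disposition, events) draws from its
own seed substream with fixed consumption, so scenarios sharing a
replicate seed share enrollment and event randomness: scenario contrasts
(e.g. power at 5% vs 30% discontinuation) are paired comparisons with
much smaller Monte-Carlo error than independent runs.

What the generator does **not** emulate: baseline covariates (treatment
is the only regressor), death and vital-status search (exercised by unit
tests, not the simulator), dependence between dropout and event risk
beyond the RD attenuation mechanism, non-proportional hazards,
recruitment ramp-up, and endpoint adjudication. A green simulation test
therefore establishes calibration of the *imputation-analysis-pooling
machinery* under the stated world, not robustness to every real-trial
pathology.

Classification conventions the simulator and classifier share: a subject
with an event before their scheduled discontinuation is an observed
event (never "missing"); subjects followed to death are complete data; a
study discontinuation on or after the subject's horizon `C` means the
subject was followed to the cut and is not missing (the day-of-data-cut
boundary case is classified as a completer — a deliberate choice where
the source material is silent).

## Open design choices made here

* `B` for simulation grids (10) and analysis (100): the source material
  never states its `B`; these are declared defaults, and the acceptance
  tolerances account for the extra Monte-Carlo noise.
* Placebo-arm RDs keep the placebo event rate in power scenarios (only
  active-arm RDs are attenuated) — implied but not stated in the source.
* RD attenuation applies over the subject's whole follow-up rather than
  switching at the treatment-discontinuation day; a piecewise switch
  variant would be a straightforward extension but is not what the
  stated rate description says.
* Discontinuation counts are fixed per arm (`round(q * n_arm)`) rather
  than binomial, so the realized missingness fraction matches the
  scenario label; RD counts likewise.
* Joint estimation of the PWE cut points is not attempted: cuts are
  fixed at quantiles (or user-supplied), which is how the worked
  analyses use the model.

## Known limitations

* The PWE arm needs enough RD events to identify one hazard per piece;
  in very sparse scenarios a few percent of simulation replicates fail
  by design (reported, never silently dropped or absorbed).
* MCMC posterior sampling is not implemented (the MLE multivariate
  sampler is asymptotically equivalent and is what the reference
  simulations used); the interface leaves room for it.
* J2R exists only in the Weibull/MLE-sampling flavor.
* Delta/gamma tipping-point adjustments and copy-reference variants
  other than J2R are out of scope.

## Worked example

```{r example, eval = FALSE}
spec <- scenario_spec(N_total = 5000, rd_frac = 0.2, disc_frac = 0.15,
                      seed = 7)
trial <- simulate_trial(spec)
classify_disposition(trial)
run_mird(trial, method = "weibull", B = 100, seed = 42)
```

The pooled result prints the hazard ratio with its 95% confidence
interval and p-value, the within/between variance split, and the mean
event count per arm across imputations (the fractional event counts seen
in multiply-imputed analyses are exactly this convention).
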