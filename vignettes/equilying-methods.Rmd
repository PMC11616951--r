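---
title: "Quantifying and modelling lying behaviour in horses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and modelling lying behaviour in horses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equilying)
```

## Why lying time

Horses perform most of their resting upright, but REM sleep requires
muscle atonia and is only possible while recumbent. A horse that does
not lie down enough accumulates a REM deficit and may eventually
collapse. Total lying duration and the number of lying bouts, split into
a daytime and a night-time window, are therefore standard welfare
outcomes in equine housing studies. This package implements the full
chain from raw leg-logger output to effect estimates, together with
synthetic-data generators that make each link verifiable.

## From acceleration to posture

A logger strapped to the foreleg cannon bone measures, on its Y axis,
the component of gravity along the leg: about $-1$ g when the horse
stands (leg vertical) and about $0$ g when it lies (leg horizontal).
`threshold_classify()` applies the per-sample rule

$$\text{state}_t = \begin{cases}\text{STANDING} & y_t < -0.75\ \mathrm{g}\\
\text{LYING} & y_t \ge -0.75\ \mathrm{g,}\end{cases}$$

at 1 Hz. The boundary value $-0.75$ g itself is assigned to the lying
class; the choice is measure-zero in practice and fixed only for
determinism. `smooth_majority()` then applies a running median over 31
samples. For a binary signal the median over an odd window is exactly
the majority vote, and the two formulations are cross-checked against
each other in the test suite.

Three edge rules are not dictated by the measurement principle and are
the package's own choices:

* **Series edges.** The first and last 15 s use a truncated, still
  centred window. Truncation can produce ties; ties resolve to
  STANDING, the conservative direction (no lying time is fabricated at
  window edges).
* **Missing samples.** Dropouts carry no vote; a window with no
  observed sample stays missing. A dropout should not manufacture
  posture evidence.
* **Gap filling.** Before classification, `fill_short_gaps()` carries
  the last observation forward across dropouts of at most 5 s (a
  config knob). Longer gaps stay missing and simply reduce the observed
  time; they never split or merge evidence. The 5 s default reflects
  that sub-window dropouts should not create spurious bouts while long
  outages should not be invented away.

### What the filter does and does not guarantee

Away from the edges, a 31 s majority filter removes any noise run that
is isolated inside a stable context, and on inputs whose true runs all
span the window it is the identity. It is tempting to state a stronger
guarantee — "no output run shorter than 16 s" — and the package tests
this on signals in the filter's operational regime (bouts of at least
the window length plus isolated noise flips). As a universal claim,
however, it is false for any single-pass (indeed any iterated) running
median: a strictly alternating sequence keeps 16 samples of the
opposite parity in every centred window and is therefore a fixed point
of the filter, 1 s runs and all. The unit tests document this
counterexample explicitly. For accelerometer noise of realistic size
(the flip probability at 0.05 g noise on a 1 g level separation is
below $10^{-6}$ per sample) the operational regime is the relevant one.

## Bouts and per-hour metrics

`segment_bouts()` turns maximal runs of one non-missing state into
bouts; a missing run terminates the current bout. Bouts therefore tile
the observed time exactly, which yields a convenient identity: the
observed time inside any window equals the summed overlap of all bouts
with that window. `compute_metrics()` clips bouts to the day window
(08:30–16:00) or night window (17:00–07:30 next day, attributed to the
evening's date) and reports

* `n_bouts_per_h`: lying bouts with positive overlap, per observed hour;
* `lying_h_per_h`: clipped lying time per observed hour, in $[0,1]$.

Normalising by *observed* (non-missing) rather than nominal hours keeps
dropout from biasing rates. A bout straddling a window boundary is
clipped for duration but counted once if any overlap remains; the
alternative (counting only fully contained bouts) would break the
conservation identity, and boundary-straddling bouts are rare in
practice because the boundary hours are used to move horses between
stable and paddock.

## The crossover design

`generate_schedule()` allocates, for each horse and repetition, one of
the $3! = 6$ orderings of the daytime conditions such that (i) every
horse uses different orderings in its repetitions, and (ii) ordering
usage across all horse-repetitions is as even as possible: each at
least $\lfloor N/6\rfloor$ times with the $N \bmod 6$ surplus drawn at
random. At the reference size (10 horses, 2 repetitions) this gives the
characteristic pattern of four orderings used three times and two used
four times. Allocation is by random dealing with a deterministic repair
pass (swapping a duplicated ordering with a horse not holding it), and
is reproducible from the seed. Calendar dates come from a user-supplied
pool of available days — in practice the days the farm sets aside — or
from synthetic consecutive dates sized so that roughly three horses
share each observation date, which is what makes the calendar-date
random effect identifiable. More than 6 repetitions per horse is
reported as infeasible rather than silently relaxing the distinctness
constraint.

## The mixed model

Both outcomes are analysed on the log scale:

$$\log(y_{hdcw} + c) = \mu_{cw} + a_h + b_d + \varepsilon_{hdcw},$$

with a full condition × time-of-day interaction ($\mu_{cw}$, 6 cells),
crossed random intercepts for horse $a_h \sim N(0, \sigma^2_H)$ and
calendar date $b_d \sim N(0, \sigma^2_D)$, and residual
$\varepsilon \sim N(0, \sigma^2)$. `fit_lmm()` estimates this by REML
(or ML) profiled deviance via `lme4::lmer`, with variances bounded at
zero. Point estimates coincide with what a Bayesian fit under flat
priors would report as posterior modes, which is why the factor
estimates of such analyses are reproducible by this likelihood route.

**Offset.** Some horses do not lie at all in some day windows, so
$y = 0$ occurs and $\log$ needs an offset. The default
`default_offset()` is half the smallest observable nonzero value of the
outcome given the windows present in the data — half of one bout per
observed hour for the bout rate ($0.5/14.5$ when night windows are
present; the day-window instance of the same rule is $0.5/7.5$), half
of one second of lying per observed hour for the duration — and exactly
0 when all outcomes are positive. The offset is a config knob, is
recorded on every fit and in all outputs, and can be varied for
sensitivity analysis. How a given historical analysis handled zeros is
usually unknowable; an explicit, reproducible rule is the best
available substitute for that ambiguity.

**Contrasts.** Effects are reported as multiplicative factors:
condition contrasts are differences of condition cell means averaged
with equal weight over the two windows, the time-of-day contrast
averages equally over the three conditions, both exponentiated. These
marginal means are checked against `emmeans` in the tests. Note the
factors apply to $y + c$; with the default offsets $c$ is either 0 or
far below the outcome scale, so the distinction is immaterial in
practice.

**Tests.** `pb_test()` implements parametric-bootstrap likelihood-ratio
tests: both models of a nested pair are fitted by ML, the observed
$\mathrm{LRT} = 2(\ell_1 - \ell_0)$ is referenced against refits on
`n_boot` datasets simulated from the fitted null, and
$p = (1 + \#\{\mathrm{LRT}^* \ge \mathrm{LRT}\})/(B+1)$. The term
structure had to be fixed by interpretation (reports of a "global
test", a condition main effect and an interaction rarely print the
model pairs): GLOBAL compares `condition*window` against `window`,
CONDITION compares `condition+window` against `window`, WINDOW
compares `condition+window` against `condition`, INTERACTION compares
`condition*window` against `condition+window`. Bootstrap refits reuse
the parent fit's structure; replicates that fail are dropped and
counted, with an error above a 5% failure rate.

**Intervals.** `pb_confint()` simulates from the fitted full model,
refits, and takes percentile intervals of the exponentiated contrast.
Percentile was chosen over basic/BCa as the most common default where
the flavour is unreported; at the reference dimensions its coverage for
the night/day duration ratio measures ≈0.95 (it is checked in the
acceptance tests at 200 simulation runs with 299 bootstrap draws —
percentile quantiles need a few hundred draws before discretisation
error becomes negligible).

## The synthetic generators

`simulate_trace()` draws an alternating renewal process: standing and
lying sojourns alternate, each from a lognormal (default, right-skewed,
`sdlog = 0.6`) or exponential distribution, and the 1 Hz signal is the
state level ($-1$/$0$ g) plus Gaussian noise. Defaults describe a young
stabled horse: mean standing bout 2.5 h, mean lying bout 30 min, hence
a lying fraction near $1/6$ (≈4 h/day — young horses lie noticeably
longer than mature ones), and 0.05 g sensor noise. The exact sojourn
list is returned so recovery can be scored against truth; a
`min_bout_s` floor lets tests construct the regime in which recovery is
provably exact.

`simulate_experiment()` generates outcome tables exactly under the
model above. The default cell means encode the magnitudes around which
the analysis is designed: night/day duration ratio 11.25 (0.25 h/h at
night in the box vs 0.022 by day), day/night bout-rate ratio 1.21 (0.36
vs 0.30 bouts/h), and mild monotone condition effects (1.08/1.17 for
bouts, 1.39/1.38 for duration) applied uniformly across windows. The
default variance components ($\sigma^2_H = 0.2$, $\sigma^2_D = 0.1$,
$\sigma^2 = 0.5$ on the log scale) put most variability within
horse-days, consistent with the wide condition-factor intervals such
studies report (a log-scale contrast SE near 0.35 at 10 horses).

What the experiment generator does *not* emulate: the lognormal
back-transform can exceed 1 h/h for the duration outcome (real metrics
cannot), there is no circadian structure within windows, no weather, no
sex/age covariates, and no dependence between the bout-rate and
duration outcomes of the same horse-period. Passing tests therefore
demonstrate correctness of the estimation machinery under the model's
own assumptions, not robustness to their violation on real recordings.

## Numerical and reproducibility choices

* All timestamps are local clock time stored as UTC; windows are
  clock-based, so no daylight-saving arithmetic is ever applied.
* All randomness flows from explicit seeds; the pipeline draws
  per-period and per-model sub-seeds once up front, so stage outputs do
  not depend on each other's RNG consumption, and a rerun with the same
  config reproduces every output byte for byte.
* `lme4` fits use `calc.derivs = FALSE` (speed) and treat singular fits
  as valid boundary estimates; convergence messages are recorded on the
  fit object.
* Simulation sizes in the acceptance tests are chosen to finish on one
  CPU: 300 replicates for parameter recovery, 120 outer × 99 bootstrap
  for test calibration, 200 runs × 299 bootstrap for interval coverage,
  100 seeds for trace-recovery tolerance.

## Known limitations

* The minimum-run guarantee of the majority filter is conditional (see
  above); adversarially oscillating inputs pass through unchanged.
* Percentile bootstrap intervals at 10 horses can undercover slightly
  for contrasts dominated by the horse variance; the night/day and
  condition contrasts used here are residual-dominated, where coverage
  is nominal.
* The logger dialect is configurable but only one file layout
  (timestamp + Y acceleration) is supported; multi-axis processing is
  out of scope.
* `refit_published_models()` will reproduce archived factor estimates
  only up to the zero-handling of the original analysis, which must be
  matched via the offset knob.
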