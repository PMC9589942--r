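---
title: "Designing contrast response experiments with crfdk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing contrast response experiments with crfdk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crfdk)
```

## The model

A visual neuron's contrast response function (CRF) is modelled by the
Naka-Rushton equation

$$ r(c) \;=\; R_{max}\,\frac{c^{\,n}}{c^{\,n} + C_{50}^{\,n}} \;+\; B $$

with the dynamic range $R_{max}$ (spikes/s), half-saturation contrast
$C_{50}$ (percent, in $(0,100]$), steepness exponent $n>0$, and baseline
$B \ge 0$ (the response at 0 % contrast, i.e. to a blank). The curve is
non-decreasing in contrast and saturates below $R_{max}+B$. At $c=0$ the
power term vanishes for every $n>0$, so 0 % contrast is a legal input even
though $C_{50}$ itself must be positive.

Spiking is modelled as a nonlinear–Poisson cascade: the stimulus contrast
is pushed through the equation to obtain a firing rate that is **constant
within a trial** — no receptive-field temporal dynamics, no refractoriness
— and spikes are drawn from a Poisson process at that rate. Because the
rate changes across randomly ordered stimuli, the process is inhomogeneous
over the experiment. This deliberately minimal generative model is what
makes million-fit design sweeps affordable; its known omissions are
discussed at the end.

## Fitting

`fit_crf()` minimizes the sum of squared errors between the model curve and
the trial-averaged mean rates, using the bounded trust-region
Levenberg–Marquardt solver of `minpack.lm` with at most 1000 iterations and
function/parameter tolerances of $10^{-11}$. SSE is the objective; the RMS
statistics below are evaluation-only.

**Bounds.** All parameters are box-constrained: $C_{50} \in (0, 100]$,
$n \in (0, 6]$ (larger exponents are neither biologically nor statistically
meaningful), and $R_{max}, B \in [0, \mathrm{MAX} + \mathrm{MAXERR}]$,
where MAX is the largest observed mean rate and MAXERR is two standard
deviations of the per-trial rates at that contrast (`derive_bounds()`).
Degenerate cases are resolved conservatively: a single trial (or
deterministic rates) sets MAXERR to zero, and a silent unit receives a
nominal $10^{-3}$ sp/s ceiling so the box never collapses. The open lower
limits of $C_{50}$ and $n$ are implemented as $\varepsilon = 10^{-6}$.

**Multistart.** Initial vectors are drawn uniformly within the box (500
restarts by default), preceded by one deterministic heuristic start
(baseline from the minimum rate, range from the span, $C_{50}$ at the first
half-rise contrast, $n=2$). Two pragmatic choices depart from a purely
blind restart loop:

- *Early exit*: once a restart's SSE falls below `sse_tol` ($10^{-12}$),
  the loop stops — the multistart exists to escape local minima, and no
  later restart can improve on an essentially zero residual. On noisy data
  this never triggers; on noise-free data it makes exact-recovery checks
  nearly free.
- *Configurable restart count*: simulation sweeps perform hundreds of
  thousands of fits on well-behaved synthetic rates, for which 6–12 random
  restarts plus the heuristic start reliably reach the global minimum; the
  default remains 500 for one-shot fits on real data.

The fit is reproducible bit-for-bit under a `seed`, and `converged` records
whether any restart met the first-order tolerance (a non-converged best
solution is still returned, flagged).

**Bounds in recovery studies.** The data-driven $R_{max}$ cap is the
estimation procedure's own defence against runaway amplitudes, and it is
the default everywhere the pipeline fits data. It is, however, *not* used
when the package tests parameter recovery against known ground truth: for
shallow curves (low $n$, high $C_{50}$ — e.g. $R_{max}=32$, $C_{50}=80$,
$n=1$) the observed maximum $r(100)$ is only $\approx 0.56\,R_{max}+B$, so
the cap excludes the true $R_{max}$ by construction and exact recovery is
impossible for any fitter. Recovery checks therefore pass explicit generous
bounds (`fit_bounds(100)`, covering the full simulation design range),
which tests the solver rather than the cap.

## Error estimators

Three estimators compare an experimental CRF against its reference:

- `rms_at_points()` — $\sqrt{\sum_i (E_i - T_i)^2 / N}$ at exactly the
  sampled contrasts, where $E$ is the fitted experimental curve and $T$ the
  reference curve.
- `rms_allpoints()` — the same statistic on a dense grid; the convention
  here is 100 linearly spaced contrasts on $[0, 100]$.
- `angle_error()` — the angle between the raw parameter 4-vectors
  $[R_{max}, B, C_{50}, n]$ in their native units (spikes/s, spikes/s,
  percent, dimensionless), $\arccos$ of the normalized dot product, clamped
  against floating-point overshoot. No unit harmonization is applied: the
  measure is scale-invariant per vector but intentionally weights the
  components as printed.

For the growing-window analysis the three errors are expressed as
percentages (`percent_variation()`). The reference scales are a
documented convention of this package: the mean of the reference curve over
the 100-point grid for both RMS errors, and $\pi/2$ (the maximal angle
between non-negative vectors) for the angle. Both are plain arguments, so
other normalizations can be substituted.

## Contrast scales

`scale_table()` lists the ten spacings. Logarithmic scales place points
between decades $10^a$ and $10^b$ and weight by 100; linear scales span a
fraction range. Pure log spacing cannot produce 0 % contrast, yet a point
at 0 is what anchors the baseline $B$ — so for every scale except scale 6
the first point is forced to exactly 0 and the remaining $n-1$ points
follow the scale's spacing (for scale 1, whose natural first point is
already 0, all $n$ points come from the spacing). Scale 6 is deliberately
the no-zero control: all its points come from its log spacing and its
baseline must be inferred from non-zero contrasts, which is precisely why
it performs poorly. Scales whose upper bound is below the full range
(3, 7, 8, 9, 10) top out below 100 %.

`map_to_available()` maps ideal scale contrasts onto the list actually
measured: nearest neighbour, ties to the lower contrast, collisions
resolved greedily in increasing order so the requested count is preserved.

## Design optimization

A **pattern** is the tuple {#points, #trials, trial length}; its recording
time is the product of the three (6 points × 2 s × 10 trials = 120 s). The
standard grids are 6 point-counts × 7 trial-counts × 6 lengths = 252
patterns, and 5 × 5 × 3 × 4 = 300 functional parameter combinations.

`run_monte_carlo()` crosses functional truths × patterns × scales ×
replicates; each cell simulates mean rates through the cascade (the
count-level shortcut `simulate_rates()` is distributionally identical to
drawing spike times, because the within-trial rate is constant), fits under
the data-driven bounds, and scores the three errors. Failures are flagged
rows, never aborts.

**Marginal profiles.** When profiling one condition
(`condition_profiles()`), the other two are held at 6 points, 2 s, 10
trials — the package's reference condition, chosen as the canonical worked
example of the estimation procedure; the profile function takes `fixed` as
an argument so other anchors can be used. Under this convention the
repetition count is the condition whose increase stabilizes the fit most,
followed by trial length, then number of points — reproduced as a
directional property in the test suite, since the exact means depend on the
anchor.

**Trade-off point.** Better patterns cost more time, so the optimum is
defined as the crossing of two curves over the error-sorted patterns: the
min-max-normalized mean error and the min-max-normalized $\log_{10}$
recording time (the logarithm deliberately amplifies the cost of long
recordings). `find_tradeoff_point()` returns the first index at which
normalized error meets or exceeds normalized time; if the curves never
cross (e.g. a flat error curve), the boundary index is returned with a
warning flag. Min-max normalization is this package's convention for
placing the two differently scaled curves on a common axis; sorting is by
error ascending.

## Validation on rich recordings

The empirical arm inverts the logic: instead of simulating from known
parameters, it takes a *rich* recording (many contrasts × many trials ×
long trials), fits the full data to define the unit's reference
("theoretical") CRF, and then asks how well each candidate pattern's
cheaper subsample reproduces it.

Conventions, in pipeline order:

- Units with a mean rate below 3 spikes/s at the maximal contrast (best
  direction, boundary inclusive) are excluded (`unit_inclusion_filter()`).
- The preferred direction maximizes the rate at maximal contrast; ties go
  to the lowest direction index.
- Subsampling (`subsample_pattern_errors()`): contrasts come from
  `generate_scale()` mapped onto the measured list; trials are drawn
  uniformly **without replacement**; the trial window is the **first**
  `trial_length` seconds from stimulus onset (onset-anchored, not a random
  window). 100 iterations by default.
- Ranking (`rank_patterns()`): per unit/scale/error kind, patterns are
  sorted from worst to best mean error; the last ten are the minimizers.
  Ties break in favour of the shorter recording time, consistent with the
  goal of minimizing recording duration.
- Consensus (`consensus_patterns()`): occurrences in the bottom-10 lists
  are counted per error kind; tier 1 = patterns present under all three
  error kinds, ordered by total count; tier 2 = present under two.
- The growing-window analysis (`dynamic_window_errors()`) recomputes rates
  from $[0, w)$ for a grid of windows, refits, expresses the errors as
  percentages of the unit's reference scale, and bootstraps the cohort mean
  by resampling units with replacement (CI collapses to the point estimate
  for a single unit).

Every dimension of the subsample is read off the pattern tuple itself — for
{6, 16, 2.0} on the rich protocol that means 6 of the 24 contrasts, 16 of
the 50 repetitions, and the first 2 s of each 4 s trial.

## The synthetic cohort

`generate_cohort()` emulates the reference protocol: 42 units, the fixed
24-contrast list (0–100 %, `cat_contrasts()`), 50 trials of 4 s per
contrast, 12 directions at 30° steps, randomized presentation. Unit truths
are sampled from the standard functional value lists; off-preferred
directions scale the contrast-driven response (not the baseline) by a
cosine-lobed tuning profile with a 0.1 floor — plumbing so that
preferred-direction selection has something to select; the pipeline never
fits direction tuning.

Adaptation is **off by default**, matching the theoretical model. When
enabled (`adaptation = list(tau, floor)`), the within-trial rate is
multiplied by $\mathrm{floor} + (1-\mathrm{floor})\,e^{-t/\tau}$ via
thinning, which lets tests probe how onset-anchored short windows interact
with decaying responses.

What the generator does **not** emulate: spike sorting artefacts,
multi-unit contamination, receptive-field dynamics, refractoriness,
inter-trial dependencies, or hysteresis. Passing tests therefore certify
the estimation and design machinery under Poisson-like variability, not
robustness to every pathology of cortical data.

## Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run scaled-down versions of the
full sweeps; sizes were fixed once as the package's own choice:

- noiseless recovery: all 300 functional combinations, 10 log-spaced
  contrasts, generous bounds;
- Poisson recovery: 20 units at the rich protocol (24 contrasts × 50 × 4 s);
- condition profiles: 27 functional combinations (3 × 3 × 3, $B=1$), the
  full condition value lists, 10 scales, 2 replicates;
- trade-off band: 8 functional combinations ($R_{max}$ {7,16} × $C_{50}$
  {40,60} × $n$ {1,3}, $B=1$), all 252 patterns, 10 scales, 1 replicate;
- growing windows: a 20-unit single-direction cohort, windows
  {0.5, 1, 2, 3, 4} s.

## Known limitations

- The within-trial rate is constant; conclusions about very short windows
  on strongly adapting neurons should lean on the adaptation-enabled
  generator, not the default.
- The angle error inherits the units of its components; a parameter with
  large numeric range ($C_{50}$ in percent) dominates the vector direction.
  It is kept as defined for comparability, not because it is statistically
  optimal.
- The data-driven $R_{max}$ cap biases fitted amplitudes downward for
  shallow curves sampled only up to 100 % contrast; this is a property of
  the estimation procedure itself and is inherited faithfully.
- Exhaustive enumeration is the optimization strategy; no gradient-based or
  Bayesian design search is attempted.
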