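---
title: "Separating premature from anticipatory saccades: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating premature from anticipatory saccades: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculochain)
```

## The task and its two clocks

In the warned saccade paradigm a central warning stimulus (WS) is flashed,
its offset starts a foreperiod of 400, 900, 1400 or 1900 ms (equiprobable),
and the imperative stimulus (IS) then appears at an eccentric position. In
the *explicit* condition a pre-trial cue lasts exactly as long as the
upcoming foreperiod, making IS timing predictable; in the *implicit*
condition only the passage of time itself is informative.

Every latency lives on one of two clocks. The **WS clock** counts from WS
offset and is natural for movements planned from the warning; the **IS
clock** counts from IS onset and is natural for visually-triggered
movements. The two are linked trial by trial through the identity

$$\mathrm{lat}_{ws} = \mathrm{lat}_{is} + \mathrm{FP},$$

which the trial-table validator enforces exactly (tolerance $10^{-9}$ ms).
A negative IS-clock latency means the eye moved before the target appeared.
Trials are stored in a TSV with a fixed thirteen-column order; missing
values are empty fields, and the medication level "not applicable" is
spelled `NONE` so that the empty string can remain the only missing-value
token.

## Trial classification

A saccade with IS-clock latency at or below the cut-off is **early** (`e`);
above it, **visually guided** (`v`); a trial without a scorable saccade is
**failed** (`f`). The boundary convention is inclusive: a latency exactly
at the cut-off is early. Saccades slower than 1000 ms (configurable) are
implausible as visual responses and are relabelled failed. The default
cut-off is 170 ms.

`detect_cutoff()` offers a data-driven alternative: the cumulative count of
IS-clock latencies rises slowly while only early saccades accumulate and
then turns abruptly when the dense visually-guided mass begins. We fit a
continuous two-segment piecewise-linear model to the cumulative count
evaluated on a uniform 1 ms grid across the search window, by least squares
over every candidate breakpoint (ties to the smaller). Evaluating the curve
on a uniform latency grid — rather than per observation — keeps the dense
visual mass from dominating the fit. Two degeneracy guards return the fixed
cut-off instead, flagged with a reason: fewer than 50 latencies, or a
right/left slope ratio below 3 at the best knee (a unimodal sample produces
a knee on its saturating flank with ratio near or below 1, never the
order-of-magnitude contrast of a genuine early/visual transition). On
smooth synthetic data the least-squares knee sits where the visual mass
overtakes the early mass — tens of ms right of the nominal cut-off — which
is why the pipeline uses the fixed 170 ms value by default and treats
detection as a diagnostic.

Saccade onset detection in raw traces uses a 5-sample moving average, a
central-difference velocity estimate, and a 30 deg/s threshold, one onset
per supra-threshold episode. Only the threshold is a scientific choice; the
smoothing is stated for reproducibility.

## The two-component latency mixture

Early-saccade latencies on the WS clock are bimodal: a premature mode near
250 ms after WS offset and an anticipatory mode that scales with the cued
duration. Within each group × condition cell and cued duration we fit

$$f(x) = \lambda_1\,\varphi(x;\mu_1,\sigma_1) +
         \lambda_2\,\varphi(x;\mu_2,\sigma_2)$$

by EM. Numerical choices, all stated so the fit is reproducible without
reference to any particular mixture package:

* initial means at the 25th/75th sample percentiles, both sds at the sample
  sd, weights $1/2$;
* 5 restarts; restarts 2–5 perturb the initial means by up to ±10% of the
  inter-initial-mean spread. The jitter is additive, which keeps the whole
  fit shift-equivariant (fitting $x + c$ moves means and cut by exactly
  $c$) — a property the test suite asserts;
* convergence when the relative log-likelihood change drops below
  $10^{-8}$, at most 1000 iterations; the log-likelihood trace is stored
  and checked to be non-decreasing;
* component sds floored at 1 ms so duplicated latencies cannot blow up the
  likelihood; a restart whose component collapses onto the floor with
  vanishing weight is discarded as degenerate;
* components reported in order of increasing mean.

The premature/anticipatory **cut** is the latency where the two weighted
component densities cross: taking logs turns
$\lambda_1\varphi_1 = \lambda_2\varphi_2$ into a quadratic (linear for
equal variances), and we keep the root in $(\mu_1, \mu_2)$ at which
dominance flips from component 1 to component 2 moving rightward. With
equal weights and equal variances this is exactly the midpoint of the
means. If no crossing exists between the means (one component dominates
everywhere), the caller may fall back to the midpoint; the per-duration
driver `fit_mixture_cuts()` does so and flags it. Cells with fewer than 30
early saccades fall back to a fit pooled across durations, also flagged.
Early saccades at or below the cut for their duration are labelled
`first`, the rest `second`; a latency exactly at the cut goes to `first`
(deterministic tie rule). Mixing proportions per duration report
`first/(first+second)` with patients' ON and OFF sessions pooled by
default (a `split_medication` flag keeps them apart).

## Markov chains over trial sequences

Trials within a block form an ordered state sequence; transitions never
span subjects or blocks. The three-state alphabet `{e, v, f}` has 9
possible transitions; splitting early saccades gives `{first, second, v,
f}` and 16. The four-state analysis runs only on explicit-condition data by
default, where early saccades are numerous enough to subdivide.

**Markov property screen.** For each state $s$, positions with current
state $s$ are stratified and the (previous state) × (next state)
contingency table is tested for independence by Pearson chi-square; under a
first-order chain, past and future are conditionally independent given the
present. Statistics and degrees of freedom are summed over strata; strata
collapsing below 2×2 are skipped with the degrees of freedom adjusted. The
screen runs per subject at $\alpha = 0.05$ (the conventional default for
this style of test, intentionally stricter than the package-wide 0.01 so
that doubtful subjects are excluded rather than retained), and subjects
that fail are dropped from pooled fits. Simulation shows the test holds its
type-I rate (0.03–0.07 at $\alpha = 0.05$ over 1000 chains of length 2000)
and rejects a strongly second-order alternative essentially always.

**Estimation.** Pooling sums per-subject within-block adjacent-pair counts;
$\hat p_{ij} = n_{ij}/n_i$ is the MLE. Rows for unvisited origin states
propagate as `NA`, never 0. Cellwise intervals are Wald,
$\hat p \pm z\sqrt{\hat p(1-\hat p)/n_i}$, clipped to $[0,1]$ (Wilson
available behind a flag); the default level is 99%, matching the
package-wide $\alpha = 0.01$. Two probabilities are compared through the
confidence interval of their difference,
$se = \sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}$, at level
$1 - \alpha/m$ for $m$ planned comparisons (Bonferroni; $m = 3$ gives the
conventional $p < 0.003$ criterion for three group comparisons). Row
uniformity is tested by Pearson chi-square against equal expected counts.

## Density and distribution comparisons

Kernel densities use a Gaussian kernel whose *standard deviation* is the
stated 40 ms width — "width" is ambiguous between sd and FWHM, and we adopt
the sd reading, configurable. The density is the exact mean of kernels
(no FFT binning) on a 1 ms grid spanning the data ± 6 bandwidths, so the
trapezoid integral is 1 within $10^{-6}$. Differences interpolate both
densities onto the union grid (zero outside their own support) and
subtract; equal bandwidths are required.

The two-sample Kolmogorov–Smirnov statistic is
$D = \sup_t |F_1(t) - F_2(t)|$ with $Z = D\sqrt{n_1 n_2/(n_1+n_2)}$ and the
p-value from the asymptotic Kolmogorov series — the convention implied by
reporting a "Z test" — with the exact small-sample distribution behind a
flag. Latencies are pooled across subjects per cell before testing, so the
reported $n$ are trial counts. OLS slope summaries report the standardised
slope $\beta = b\,sd(x)/sd(y)$, $t$, $F = t^2$ and $r^2$ for the
latency-versus-duration regressions that contrast the weakly cue-dependent
premature mode with the strongly cue-dependent anticipatory mode.

## The synthetic cohort generator

No public recordings exist for this paradigm, so the generator is the
package's test bed: a latent four-state Markov chain (`first`, `second`,
`v`, `f`) drives trial states, and latencies are drawn conditional on the
state:

* premature: WS-clock Gaussian, mean $250 + 0.05 \cdot \mathrm{cue}$ ms
  (the cue term only in the explicit condition), sd 60 ms;
* anticipatory: WS-clock Gaussian, mean $300 + 0.75 \cdot \mathrm{FP}$ ms,
  sd 90 ms — scaling with the foreperiod so the movement lands near the
  expected IS, with the 400 ms duration too short for anticipation to
  land before the cut-off (as observed empirically);
* visually guided: IS-clock Gaussian, mean 319 ms (controls) or 376 ms
  (patients), sd 50 ms, truncated above the cut-off so a visual trial can
  never be labelled early;
* failed: no latency. All latency draws are truncated at zero (redrawn),
  a slight truncation of the Gaussian tails.

Foreperiods are uniform over the four values; the initial fixation duration
is uniform on [750, 950] ms (a uniform reading of "850 ± 100 ms"; it does
not enter any analysis). Transition probabilities that are printed in the
source condition are used verbatim — implicit-control `e→e` 0.17 and `e→v`
0.64; explicit `first→first` 0.12 / 0.20 / 0.30 and `second→second` 0.53 /
0.26 / 0.10 for control / ON / OFF — and the remaining cells are fill-ins
chosen so stationary occupancies approximate the observed response-type
percentages (about 6/74/20 early/visual/failed for implicit controls,
18/63/19 explicit; patients with elevated failure rates). Fill-ins are
documented approximations, not ground truth. Implicit-condition matrices
are specified in the three-state alphabet plus an early-mode split
probability and expanded to four states with identical `first`/`second`
rows; `collapse_latent4()` merges back using stationary weights.

Two latency profiles are provided. `"realistic"` keeps the overlap
structure of real data: anticipatory saccades at short durations often land
after the cut-off and are *observed* as visually guided, exactly the
leakage a real analysis faces. `"well_separated"` tightens the sds, moves
the anticipatory mode well inside the cut-off and truncates early modes at
the cut-off, making latent states and observable labels coincide — the
regime for recovery benchmarking, where the separation between modes
exceeds 4 pooled sds at every duration. Per-subject seeds derive from the
master seed by a Lehmer-style integer scramble, so enlarging a cohort never
perturbs existing sessions.

What passing tests on synthetic data do **not** show: the generator draws
Gaussian latencies, has no drifts, blinks, fatigue or learning, no
between-subject heterogeneity in transition probabilities, and its failed
trials are latent states rather than consequences of gaze artifacts. Tests
demonstrate that the estimators recover the structure they assume, not that
real recordings satisfy those assumptions.

## Problem sizes and design choices in the checks

The acceptance-style checks run at sizes chosen to make sampling error
comfortably smaller than the asserted tolerances on a single CPU: 20
replicates of $n = 1000$ for mixture recovery; 100 random parameter sets
against a 0.01 ms grid for the analytic cut; 1000 fuzzed sequence sets for
the transition MLE; 1000 chains of length 2000 for type-I calibration;
single 20 000-trial sessions (and 100 replicates for CI coverage) for
end-to-end recovery, where every estimated transition probability falls
within ±0.03 of its generating value and 99% Wald intervals cover at
essentially the nominal rate; cohorts at the study's own sizes (18
controls, 20 patients, ~200 trials per session) for the qualitative
signatures.

Genuinely open choices made here, with their reasons: the per-duration
mixture fits pool subjects within a cell (sequence analyses pool the same
way, and per-subject per-duration early counts are far too small); the
Markov screen level is 0.05 rather than the package-wide 0.01 (exclusion
should be conservative about retaining doubtful subjects); Wald rather than
score intervals cellwise (simplicity and symmetry with the
difference-of-proportions comparison, Wilson available); breakpoint
detection is offered but not the default (its knee is systematically right
of the density onset on smooth data, see above).

## Known limitations

The Markov-property statistic is a triplet-stratified chi-square — a
faithful, documented stand-in for the equivalent conventional test, not a
byte-for-byte reimplementation of any particular package's version.
Four-state estimates under the realistic latency profile are attenuated by
classification leakage (anticipatory trials at short durations observed as
visual); this mirrors real analyses and is why recovery benchmarks use the
well-separated profile. The generator's unprinted matrix cells are
approximate fill-ins; conclusions that depend on them (stationary
occupancies, exact failure rates) are illustrative only.
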