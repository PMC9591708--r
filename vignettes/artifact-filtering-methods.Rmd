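---
title: "Artifact filtering and agreement evaluation for intraoperative temperature traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact filtering and agreement evaluation for intraoperative temperature traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoclean)
```

## The problem

Core temperature during general anesthesia is charted automatically from
nasopharyngeal or oropharyngeal probes, typically about once a minute. A
small fraction of readings — on the order of 1% — do not reflect the
patient's core temperature: the probe falls out and reads toward ambient
temperature, a freshly (re)inserted probe spends a few readings warming up
from room temperature, or implausible values are charted after a gap in data
capture. Left in place, such artifacts distort exactly the quantities
observational anesthesia research cares about, above all the *hypothermia
burden*: the area between a 36 °C line and the temperature curve wherever
the curve is below it, in minutes·°C, which combines the duration and the
severity of intraoperative hypothermia in one number.

`thermoclean` implements two automated artifact filters for such traces and
the full statistical apparatus needed to evaluate a filter against expert
adjudication: consensus labeling, sensitivity/specificity/F-score,
chance-corrected inter-rater agreement (Gwet's AC1), Bland–Altman limits of
agreement on per-case summaries, leave-one-out jackknife diagnostics, and
prospective sample-size planning for agreement studies after Lu et al.
(2016). Because registry traces cannot be redistributed, the package ships a
seeded generator of anesthesia-typical traces with truth-labeled injected
artifacts; every pipeline stage is testable end to end without patient data.

## The two filters

Both filters start from the same *plausibility bounds*: readings strictly
below 32 °C or strictly above 40 °C are physiologically implausible during
anesthesia and are flagged unconditionally. Readings exactly at a bound are
retained — every threshold comparison in the package is strict, mirroring
the "greater than"/"less than" phrasing the thresholds were defined with.

Both filters then process the surviving readings left to right, and both
remove a confirmed artifact from consideration *before* later decisions are
made, so that every subsequent comparison anchors on the last reading still
considered valid. This sequential semantics mirrors how a human reviews a
chart: once a value is recognized as garbage, it no longer serves as
context.

### Algorithm 1 — the slope filter

For each window of three consecutive surviving readings, the
ordinary-least-squares slope of temperature on time is computed. If its
magnitude strictly exceeds `slope_threshold` (default 0.08 °C/min), the
window's **newest** reading becomes a candidate; the candidate is confirmed
as an artifact when its absolute change from the previous surviving reading
strictly exceeds `jump_threshold` (default 0.25 °C). Requiring both
conditions lets steep-but-smooth physiological rewarming (large slope, small
per-reading jumps) and long-interval drift (large jump impossible; slope
diluted by the wide window) pass untouched.

Two design choices deserve comment:

* **Units of the 0.08 threshold.** The slope is in °C per minute, the same
  units as the interval filter's 0.35 °C/min bridge threshold; consistency
  across the two rules is the only defensible reading, and the value is
  configurable in any case.

* **Which window reading is the candidate.** The candidate is the window's
  newest (third) point, not its center. This matters: a line fitted through
  the three points *centered* on a symmetric one-reading dip has slope
  exactly zero, so center attribution is structurally blind to precisely the
  probe-fall-out dips the rule exists to catch — and worse, the window
  centered on the *next* (valid) reading then fires and removes a good
  value. Trailing attribution fires on the dip's falling edge, flags the dip
  itself, and, because windows are keyed by their newest point, a removal
  never alters an already-inspected window — one forward pass is provably
  identical to naively rescanning every window from scratch after each
  removal (the property the test-suite oracle checks). A consequence is that
  the first two surviving readings of a trace can never be slope candidates;
  they remain excludable by the plausibility and gap rules.

The slope is signed-blind: `|slope|` is compared, because artifacts include
both dips (fall-out) and fast rises (warm-up). A trace with fewer than three
surviving readings gets no slope flags and a warning.

### Algorithm 2 — the interval filter

The filter looks for *recording gaps*: intervals between consecutive
surviving readings strictly longer than `gap_threshold` (default 5 min).
The readings after a gap, up to the next gap or the end of the trace, form a
segment:

1. a segment with fewer than `min_readings_after_gap` (default 5) readings
   is too short to re-establish trust and is flagged wholesale;
2. otherwise the *bridge slope* from the last valid pre-gap reading to the
   segment's first reading is computed; if its magnitude is strictly below
   `gap_slope_threshold` (default 0.35 °C/min) the segment is retained;
3. otherwise that first reading is flagged and the bridge is retried against
   the segment's next reading, one reading at a time, until a bridge holds
   or the segment is exhausted.

Flagging one reading per retry (rather than discarding the segment at the
first failed bridge) is the conservative reading of the rule's loop
structure, and is isolated in one code path should the aggressive variant
ever be wanted. Bridges always anchor on the last *valid* reading, skipping
anything already flagged — including entire short segments — so a sequence
of gaps degrades gracefully. The opening segment of a trace follows no gap
and is never flagged by this rule. A segment with no valid reading anywhere
before it has no bridge anchor and is retained.

## Per-case measures

`hypothermia_auc()` integrates the deficit below the 36 °C line over the
retained readings with the trapezoid rule on *clipped* heights
`h = max(0, 36 − T)`: segment area `(h_i + h_{i+1})/2 · (t_{i+1} − t_i)`.
Heights are clipped per reading and segments crossing the line are **not**
split at the interpolated crossing time by default — the deficit is a
piecewise-linear function evaluated at observed points, and plain trapezoids
on those points are the transparent choice. The exact-crossing variant
(`split_crossings = TRUE`) integrates the clipped line exactly (a crossing
segment contributes a triangle) and always gives a value less than or equal
to the default on crossing segments; the difference is second-order for
minute-level sampling. Gaps between retained readings contribute plain
trapezoid area across the gap — no imputation, which means long flagged
stretches are bridged linearly and genuine temperature excursions inside
them are invisible. That is a stated limitation, not a bug.

`mean_temperature()` is the unweighted mean over retained *readings* (not a
time-weighted average): with approximately regular sampling the two nearly
coincide, and the reading-mean is the convention in registry work.

Both measures error on zero retained readings rather than returning 0 — an
all-artifact case has no defined temperature summary.

## Evaluation statistics

* **Consensus**: `majority_vote()` labels a reading an artifact when more
  than half the raters did (2 of 3 in the canonical setup).
* **Classification**: artifact is the positive class; sensitivity
  `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`, and the
  standard F1 score. A metric whose denominator vanishes is reported `NA`
  with the vanished denominator named — never silently 0.
* **Prevalence**: `artifact_rate()` gives the binomial point estimate with a
  Wald interval by default (Wilson by option; at n in the tens of thousands
  and p near 1% the two differ in the fourth decimal).
* **Gwet's AC1** (`gwet_ac1()`): observed agreement `Pa` is the average
  pairwise agreement per item; chance agreement `Pe = 2π(1−π)` with `π` the
  artifact prevalence averaged over raters; `AC1 = (Pa − Pe)/(1 − Pe)`.
  Unlike Cohen/Fleiss kappa, AC1 does not collapse when one category is rare
  — and artifact adjudication lives at ~1% prevalence, which is exactly why
  it is the agreement coefficient of choice here. The variance follows
  Gwet's item-level estimator (Gwet 2008), with a symmetric per-item chance
  contribution `(r₁/r)(1−π) + (r₀/r)π`, and the confidence interval uses a
  t critical value with n−1 degrees of freedom, truncated to [−1, 1].
* **Bland–Altman** (`bland_altman()`): bias = mean paired difference, limits
  of agreement = bias ± 1.96·SD (sample SD, n−1). The 1.96 multiplier is
  fixed by the 95% convention.
* **Jackknife** (`jackknife_summaries()`): the chosen statistic (bias or
  either agreement limit) recomputed with each case left out;
  SE = `sqrt((n−1)/n · Σ(θᵢ − θ̄)²)`; leave-one-out estimates deviating from
  the full estimate by more than an influence threshold (default: 10% of the
  SD of the input differences) are flagged.

### Sample size for agreement studies

`agreement_sample_size()` finds the smallest n at which the probability that
both limits of agreement — together with their confidence bounds — fall
inside ±`delta` reaches the target power, iterating n upward (the power is
monotone in n, so the first crossing is the answer). The approximate power
formula follows Lu et al. (2016): with `z = qnorm(1 − (1 − confidence)/2)`
and `se = sd·sqrt(1/n + z²/(2(n−1)))`,

```
power(n) = Φ(τ₁ − crit) + Φ(τ₂ − crit) − 1,
τ₁ = (δ − μ − z·σ)/se,   τ₂ = (δ + μ − z·σ)/se.
```

Published presentations of the method differ in the critical value `crit`
for the limits' confidence bounds. The package exposes the choice as
`variant`: `"t"` (one-sided t quantile at `ci_confidence` with n−1 degrees
of freedom, the default) and `"z"` (one-sided normal quantile). The t
variant reproduces the method's worked design instance
(μ = 0.2, σ = 1.02, δ = 2.56 → n = 147, with power 0.8018 at 147 and 0.7994
at 146); the z variant lands one below. The design is infeasible — no n
ever reaches the target — unless `δ > |μ| + z·σ`, and the function says so
up front rather than iterating forever.

## The synthetic generator: its world and its limits

`generate_cohort()` emulates the statistical shape of an anesthesia registry
sample, not the physiology behind it:

| parameter | default | why |
|---|---|---|
| `n_cases` | 200 | typical validation cohort size |
| reading count | log-normal, `meanlog = log(103)`, `sdlog = 0.95`, truncated at 3 | median 103 readings per case with wide spread (quartiles ≈ 54/196), matching minute-level charting of cases from under an hour to many hours |
| `sampling_interval` | 1 min ± 25% jitter | approximately minute-level capture with irregular spacing |
| curve | 36.5 °C start, exponential cooling of 1.3 °C with 60-min time constant, +0.01 °C/min rewarming after 90 min | the canonical redistribution-then-plateau profile; all clean slopes ≤ ~0.022 °C/min, far below the filters' triggers |
| `noise_sd` | 0.02 °C | thermistor-grade noise; keeps clean per-reading jumps an order of magnitude below the 0.25 °C confirmation threshold |
| `artifact_rate` | 0.01 | the ~1% per-reading artifact prevalence of automated capture |
| `artifact_mix` | 40% fall-out dips, 30% warm-up ramps, 30% post-gap readings | the three mechanistic artifact kinds |
| dip targets | uniform on [24, 34] °C | some dips land *inside* the plausibility band so the slope rule is exercised, not just the bounds |
| `gap_rate` | 0.01 per interval | occasional benign recording gaps of 6–15 min |

Each case draws its artifact-reading budget as
`Binomial(n_readings, artifact_rate)` and composes artifact events to meet
it; this keeps the cohort-level artifact fraction concentrated like a plain
binomial (the invariant the tests assert), where naive independent event
injection would over-disperse it. Events keep five clean readings of margin
from trace ends and six from each other, and benign gaps are placed with
the same margins, so the generator's clean stretches provably stay below
every filter threshold: with artifact injection off, both algorithms flag
exactly zero readings, and the test suite asserts this.

A master seed fans out deterministically to per-case seeds, so any single
case is regenerable in isolation, and generation does not disturb the
caller's RNG stream.

`simulate_raters()` flips truth labels independently per rater (miss rate
0.2, false-alarm rate 0.025 by default); on a ~1%-artifact cohort this puts
three-rater unanimity a little above 92%, the regime of real expert
adjudication.

**What a green test does and does not establish.** Injected artifacts are
mechanistically sharp: dips drop by degrees, ramps rise at many times the
slope threshold. On such data the slope filter's sensitivity is far higher
(~0.98 on the default cohort) than on real registry data, where experts flag
subtle patterns the generator does not produce; the specificity regime
(>0.98, in practice ≈ 1.0 here) and the relative behavior of the two
filters (the interval filter misses in-band dips without gaps; sensitivity
≈ 0.56) are the transferable findings. The generator also does not model
charting quantization, probe repositioning wobble, or whole-case probe
misplacement — the last being undetectable in principle by within-trace
filters, which see only changes and gradients.

## Degenerate inputs and numerical conventions

* Times are minutes from each case's first reading; duplicate timestamps
  within a case are an error (slopes would divide by zero), not averaged
  away.
* Traces with fewer than 3 readings are ineligible (`validate_trace()`),
  matching the filters' minimum window.
* All thresholds compare strictly; boundary values are retained.
* `ols_slope()` demands three points with distinct times and errors
  otherwise.
* Every randomized routine takes an explicit seed; identical inputs and
  seeds give byte-identical outputs.

## Known limitations

* Within-trace filters cannot detect a probe misplaced for the entire case.
* Bridging flagged stretches and recording gaps with trapezoids can
  misstate hypothermia burden when true excursions fall inside them.
* The interval filter is blind to artifacts that arrive without a recording
  gap and stay inside the plausibility band.
* The printed F-score of a filter depends on reference prevalence; with
  prevalence near 1%, small absolute numbers of false positives move it
  substantially.
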