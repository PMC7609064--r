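---
title: "Models and methods behind flysleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flysleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flysleep)
```

This vignette is the package's account of its science: the models, the
conventions that had to be fixed where common practice admits variants,
the numerical choices, and the known limits of each stage. Nothing here
reports a number that the test suite or `scripts/acceptance.R` does not
itself compute.

## Sleep scoring and its conventions

Activity monitors report beam-break counts in 1-minute bins. Sleep is
scored as every maximal run of zero-count minutes of length ≥ 5; each
such run is a bout. Conventions that needed fixing:

* **Recording edges.** A zero run truncated by the start or end of the
  recording counts if its *observed* length reaches 5 min. The true
  extent is unknowable; this matches common DAM practice and is the same
  rule the expectation oracle uses.
* **Phase boundaries.** A bout spanning lights-off contributes its
  minutes to day and night *by membership* (minute at ZT 720 is night;
  day is the half-open interval [ZT 0, ZT 720) under 12:12). Whether the
  historical tools split bouts this way or assigned them to the onset
  phase is not documented anywhere we could find; minute-membership is
  self-consistent with the 30-min profile and conserves totals exactly,
  which the tests assert.
* **Windows.** Summaries are computed over complete lights-on-to-lights-on
  cycles; asking for a window the recording does not fully cover is a
  hard error rather than a silent partial sum.
* **Dead flies.** A fly whose terminal zero run reaches 12 h (configurable)
  is flagged dead from the start of that run and excluded from group
  summaries. This is an artifact-handling rule, not a biological claim.
* **Boxplots.** `tukey_box_summary()` uses linear interpolation between
  order statistics (`quantile(type = 7)`); Tukey's method admits several
  quantile variants, and the declared one is also what the test oracle
  uses. Whiskers run to the most extreme values within 1.5·IQR of the
  box.

## The two-state behavior model and its exact expectation

The generator simulates each fly as a per-minute two-state Markov chain
(wake/sleep) with phase-dependent transition probabilities: `s` =
P(fall asleep) per minute, `w` = P(wake) per minute, each possibly
different between day and night and inside thermogenetic-activation
epochs. Dwell times are geometric with means `1/s` and `1/w` minutes.
Awake minutes emit zero-truncated Poisson counts whose *mean* equals
`wake_activity_rate` (the underlying rate is solved numerically), so an
awake minute always registers at least one count and scored sleep can
discard true sleep (runs shorter than 5 min) but never invent it.

Because run lengths are geometric, the probability that a given minute is
scored as sleep has a closed form. `expected_scored_sleep()` evaluates it
exactly, including phase/epoch switching and recording edges, by a
dynamic program over run starts: the probability that minute *m* lies in
a qualifying run is the sum over start minutes *s* ≤ *m* of
P(run starts at *s*) × P(the run persists through max(*m*, *s*+4)),
with the persistence products accumulated in log space. For a homogeneous
stretch this reduces to the stationary identity
π·q⁴·(5w + q) with q = 1 − w, which the tests verify against full
enumeration of all state sequences on short chains and against
Monte-Carlo simulation. The simulator itself samples dwell-by-dwell
(restarting the geometric draw at parameter-segment boundaries, exact by
memorylessness), so simulating a fly costs hundreds rather than
thousands of RNG calls.

Each fly's RNG stream is seeded by a 32-bit hash of (base seed, fly id),
making cohorts reproducible bit-exactly and order-independent.

### Condition presets

`fly_model_preset()` encodes the qualitative structure of the
pairing-by-diet biology: normally fed MF pairs court at night (short
sleep dwells, ~3 min; nighttime sleep near 50–150 min), yeast-deprived MF
pairs and MM pairs sleep most of the night (dwells tens of minutes,
500–620 min). These are realistic magnitudes for consolidated fly night
sleep, chosen once; they are not fitted to any dataset.

`interaction_design_models()` builds the calibrated 2×2 used for power
checks: three cells share a base model with very consolidated sleep
(mean nighttime dwell 120 min, which puts the across-fly SD of scored
nighttime sleep near 120 min — the between-fly spread the design
assumes), and the fourth cell's `p_wake_night` is recalibrated by root
finding on the *exact* expected scored sleep so the interaction contrast
equals the requested number of minutes exactly. With contrast 120 min,
SD ≈ 120 min and n = 32 per cell, the noncentrality of the interaction
F-test is about 8, so rejection at p < 0.01 cannot exceed roughly
two-thirds of replicates — the acceptance suite measures and reports
this rate rather than assuming it. The null design (contrast 0) is used
to check type-I calibration.

What the generator deliberately does **not** emulate: between-fly
parameter heterogeneity within a condition, dawn/dusk transition ramps,
locomotor microstructure within awake minutes, or female behavior beyond
the pairing label. Passing tests therefore demonstrate correctness of
the scoring and statistics chain under the stated stochastic model, not
robustness to every feature of real monitor data.

### Multi-beam simulation

While awake the fly performs an adjacent-step random walk over the 17
beam positions (≥ 1 inter-beam move per awake minute, zero-truncated
Poisson) plus Poisson within-beam micro-movements; while asleep a twitch
registers in the counts channel with a small probability per minute.
`counts ≥ moves` holds minute-by-minute *by construction* and is
asserted, which forces scored sleep under counts mode to be ≤ scored
sleep under moves mode for every fly.

## Ethogram window scoring

Video-scored behavior is a per-second label over three states. For a
5-min analysis window, an immobility run qualifies as sleep if its total
extent — followed up to 300 s beyond either window edge (the context
horizon, configurable) — reaches 300 s; 300 s of context suffices
because the criterion itself is 300 s. In-window seconds of qualifying
runs are sleep; shorter immobility is "brief inactivity" and counts as
wake-but-not-courting; courting seconds count as courting. Runs
straddling the window start are treated symmetrically to window-end
runs, and the three percentages partition 100 exactly. The nightly
aggregate is the unweighted mean over the six windows starting at ZT 18,
19, …, 23 h.

## Courtship index and latency analysis

CI = courting time in [t_init, t_init + D) divided by
D = min(600 s, t_cop − t_init). Males that never initiate have an
*undefined* CI (`NA`), which is excluded from group summaries rather than
imputed as zero — an index of courtship vigor is only defined for
courting males. Latencies are measured from introduction and censored at
the 2-h observation end. The log-rank test is implemented from its
definition (observed minus expected events under risk-set proportions,
hypergeometric variance at ties, events before censorings at tied
times); the `survival` package serves as an independent cross-check in
the tests, never as the implementation.

## Calcium ΔF/F₀ with photobleaching correction

The model is F(t) = A·e^(−kt) + C fitted by least squares to the frames
in two transient-free windows: 30–60 s before ATP onset and 150–180 s
after ATP offset (half-open; a frame belongs to a window iff its
timestamp lies inside). The fit is computed by profiling: for each
candidate k the model is linear in (A, C) and solved in closed form; the
residual sum of squares is minimized over k ≥ 0. This is exactly the
least-squares estimate but avoids the divergence of a free 3-parameter
exponential when the decay is nearly flat. Two plausibility constraints
reflect what a bleaching curve is: A ≥ 0 and C ≥ 0.

* **What is subtracted.** Only the decaying term A·e^(−kt). Subtracting
  the full fitted curve would drive the baseline to ~0 and make the
  relative normalization (F − F₀)/F₀ meaningless; that literal variant is
  available behind `subtract_offset = TRUE` and fails loudly when F₀
  becomes non-positive.
* **F₀** is the mean detrended intensity over the 30 s before ATP onset.
* **Peak response.** "Peak" is not standardized; the package defines it
  as the maximum, over [ATP start, ATP end + 60 s), of the ΔF/F₀ series
  after a 45-s centered moving average (9 frames at 5-s sampling). The
  ATP response is sustained on the minute scale, so this tracks the
  plateau while keeping a single noisy frame from defining the response.
  Width and window are arguments.

**Known limit: identifiability of the offset.** The two 30-s windows sit
at the ends of a 300-s trace. When the bleach is slow (k ≲ 0.005 s⁻¹ at
this layout), the observed decay fraction is small and (A, k, C) lie on
a likelihood ridge: the Fisher information of the 12 window frames bounds
the achievable precision of C at roughly 8, 25, 60, 250 intensity units
(for C = 100, frame noise 1) at k = 0.005, 0.003, 0.002, 0.001 s⁻¹.
Since the estimated ΔF/F₀ scales as C/Ĉ, slow-bleach traces carry an
irreducible amplitude uncertainty of tens of percent, and occasionally
the best least-squares fit is a pure exponential through zero (Ĉ = 0),
in which case F₀ validation fails loudly. This is a property of the
window design, not of the optimizer; the acceptance script measures and
reports the resulting recovery rates across the k range, and the unit
tests check recovery in the identifiable regime (k ≥ 0.0065 s⁻¹, where
the bound on Ĉ is ~3%).

The synthetic traces place the evoked transient on the stable baseline:
F(t) = C·(1 + a·s(t)) + A·e^(−kt) + ε, with s(t) a 10-s ramp, plateau,
30-s decay confined to [ATP start, ATP end + 60 s] and ε Gaussian. The
amplitude is defined relative to the persistent fluorophore pool C, so
the ground-truth peak ΔF/F₀ equals `a` exactly and recovery is
measurable against it; had the transient multiplied the decaying
component as well, the "true" normalized peak would depend on A, k and
the peak time rather than being a single number.

## The statistical decision procedure

`choose_two_group_test()` encodes the decision tree as an explicit,
testable contract: D'Agostino–Pearson normality per group (implemented
from the published skewness and kurtosis transformations, since no
installed package provides the omnibus K² test; validated against frozen
reference values from an independent implementation) at α = 0.05 → if
either group fails, Mann–Whitney; otherwise Brown–Forsythe (Levene on
deviations from medians, via `car`) at α = 0.05 → Welch or Student t.
Groups below n = 8 skip the normality test (unreliable there) and take
the nonparametric branch with a warning. Gate levels and the floor are
arguments.

Two-factor designs go through `interaction_anova()` (`lm` + `anova`),
with post-hoc families delegated to `emmeans`: Tukey for all pairs
(default), Sidak for planned pairs, Dunnett against a control cell — the
family is an explicit argument because different experiments legitimately
want different families.

`screen_hits()` implements the dual-control rule: a line is a hit iff
its experimental group differs from **both** the line's Gal4 control and
the shared UAS control at α with the same sign of effect. The pairwise
comparisons are Welch t tests with a Sidak correction over the two
control comparisons (a Dunnett-T3-style procedure for unequal variances;
the exact T3 reference distribution — the studentized maximum modulus —
is not available in the supported stack, and Sidak is slightly
conservative). The reported per-line effect is the mean difference
against the shared UAS control.

## Problem sizes and determinism

The test suite and the acceptance script use the sizes the designs call
for: 10,000 random days for the scorer/oracle comparison; 200 multi-beam
flies for the moves/counts ordering; 100 replicates of the 2×2 at n = 32
per cell (effect and null); 20 replicates of the thermogenetic design at
n = 60 over 5 days; 1,000 + 1,000 calcium traces (61 frames each);
1,000 null and 400 alternative log-rank replicates at n = 40 per group;
and a 20-line screen at n = 30 per group. Everything is seeded: the
acceptance script derives every stream from its `--seed`, and the same
configuration and seed reproduce every output byte-for-byte.

## Limitations

* The monitor-file dialect is a documented, self-consistent layout in the
  spirit of the common DAM formats, not a byte-level clone of any
  vendor's; real files need a thin column-mapping adapter.
* The ethogram stage consumes labels, not video; scorer disagreement and
  frame-level ambiguity are out of scope.
* The calcium stage consumes one ROI trace; registration, segmentation
  and projection live upstream.
* Between-fly variability is represented only through the scored
  metric's sampling distribution, not through per-fly parameter
  heterogeneity; effect sizes in the simulator are therefore cleaner
  than field data at the same nominal SD.
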