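---
title: "Methods: fat-protein-unit dosing, postprandial CGM metrics and the synthetic crossover simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fat-protein-unit dosing, postprandial CGM metrics and the synthetic crossover simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpudose)
```

## The clinical problem

In type-1 diabetes, mealtime insulin is conventionally dosed by carbohydrate
counting (CC): the carbohydrate mass of the meal divided by the patient's
insulin-to-carbohydrate ratio (ICR). Dietary fat and protein, however, also
raise glucose — later and more slowly than carbohydrate, typically between
1.5 and 6 hours after eating — so CC systematically under-doses meals rich in
protein and fat. Fat-protein-unit (FPU) algorithms convert protein/fat energy
into a carbohydrate equivalent: the original Pankowska equation counts one
FPU per 100 kcal of protein + fat, a modified variant counts one per
200 kcal, and each counted FPU is dosed like 10 g of carbohydrate.

This package implements the dosing arithmetic, the full suite of
postprandial continuous-glucose-monitoring (CGM) outcome metrics used to
evaluate such algorithms over a 0-300 min window, a calibrated synthetic
four-arm crossover simulator, and the paired within-subject analysis that a
crossover trial of CC versus modified FPU supports.

## Dosing algorithms

With meal carbohydrate $C$ (g), protein $P$ (g), fat $F$ (g) and ICR $\rho$
(g/U, estimated by the 500 rule $\rho = 500/\mathrm{TDD}$):

* CC: $\;u_{\mathrm{CC}} = C/\rho$.
* FPU with energy quantum $q$ kcal/FPU ($q = 200$ modified, $q = 100$
  Pankowska): $n_{\mathrm{FPU}} = \mathrm{round}\!\left((4P + 9F)/q\right)$
  (half-up; a fractional mode skips the rounding), and
  $u_{\mathrm{FPU}} = (C + 10\,n_{\mathrm{FPU}})/\rho$.

Design notes:

* The 500 rule is used in its standard grams-per-unit form; that is the only
  reading compatible with an ICR quoted as "1 unit per $x$ g".
* FPU counting rounds half-up to a whole FPU by default, which assigns one
  FPU to the trial's normal-protein meal (281 kcal protein+fat) and two to
  its high protein-fat meal (362.5 kcal). The fractional mode exists because
  published mean administered doses reflect per-subject dose adjustments and
  match neither rounding exactly; we treat printed dose means as reporting
  arithmetic, not as an oracle for the algorithm.
* Atwater factors are fixed at 4/4/9 kcal/g; fiber contributes no energy and
  no dose. Dose-increment rounding (pen steps) applies to the total dose
  only, after summing the carbohydrate and FPU parts, and defaults to off.
* The dose ratio $u_{\mathrm{FPU}}/u_{\mathrm{CC}} = (C + 10 n)/C$ is
  independent of the ICR, which is why whole-percent dose increases can be
  checked from meal composition alone.

## CGM outcome metrics

All metrics operate on a `glucose_trace`: readings in mmol/L at strictly
increasing minutes after the first bite, with a mandatory baseline reading
$G_0$ at $t = 0$. Choices that needed making:

* **Window means** use closed intervals, so the reading at 120 min
  contributes to both the 0-120 and 120-240 windows, matching overlapping
  reporting windows.
* **Peak** is the maximum over $t > 0$ (the fasting baseline does not
  compete); ties break to the earliest time.
* **AUC** is trapezoidal. **Incremental AUC** subtracts the baseline; the
  default `net` policy keeps sub-baseline segments negative, preserving the
  identity $\mathrm{iAUC} = \mathrm{AUC} - G_0 t$. A `positive_only` policy
  truncates sub-baseline area segment-wise with linear interpolation at
  baseline crossings. `net` is the default because nadir excursions are
  reported separately (as $\Delta\mathrm{Low}$), so clipping would double-count
  protection against lows.
* **Time in ranges** uses the fraction of discrete readings, not
  interpolated durations — flash-monitor data are 15-min samples. In-range
  is the closed interval [3.9, 10] mmol/L; above/below are strict.
* **Hypoglycemic episodes** are maximal runs of readings strictly below
  3.9 mmol/L; a single reading qualifies (the source trial gives no duration
  criterion), and the onset is the first sub-threshold reading.
* **30-min excursions** require readings exactly on the 30-min grid and fail
  loudly rather than interpolate.
* **MAGE** is the single biggest interpretive choice, since the name alone
  does not fix an algorithm. We implement the classical turning-point
  definition: local extrema of the reading sequence (plateaus collapsed,
  endpoints included), amplitudes between consecutive extrema, a 1-SD
  qualification threshold (SD of all readings), and averaging only
  amplitudes in the direction of the first qualifying amplitude. Boundary
  half-swings (e.g. baseline up to the first crest) qualify like any other;
  on a sampled sinusoid this makes MAGE smaller than the crest-to-trough
  amplitude, which is the behaviour of the classical definition rather than
  a bug. MAGE is shift-invariant and scales linearly, and both properties
  are tested.

## The synthetic crossover simulator

No patient-level data are released with the source trial, so the pipeline is
exercised on synthetic data whose *structure* matches the design: four arms
(NPM/HPFM meal x CC/FPU dosing), every subject in every arm with one shared
subject profile (crossover), 15-min sampling over 0-300 min.

Each trace is a kernel superposition

$$G(t) = b + C\,s_c\,r_c(t) + E_{pf}\,s_p\,r_p(t) - u\,s_i\,r_i(t) + \varepsilon(t),$$

with unit kernels $r(t) = (t/t_p)^a e^{a(1 - t/t_p)}$ (zero at onset, unique
peak of 1 at $t_p$), AR(1) sensor noise $\varepsilon$ (stationary SD
0.35 mmol/L, $\rho = 0.5$), a 2.2 mmol/L physiological floor, and — mirroring
the trial's safety protocol — a 15-g rescue-carbohydrate response
superimposed at the onset of any below-3.9 run. A phenomenological
superposition was chosen over a mechanistic insulin-glucose ODE model
because the pipeline only needs traces with the right timing and shape
statistics, and no physiological parameters are available to fit an ODE.

**Population.** TDD is lognormal with median 31.77 U/day (the value implied
by the published mean ICR of 15.74 g/U) and log-SD 0.28 (matching the
published ICR coefficient of variation of about 0.3); fasting baseline is
Normal(6.5, 0.6) truncated to the 3.9-10 mmol/L fasting eligibility window
(the published fasting dispersion is a standard error, not an SD, so a
realistic fasting SD was chosen); per-subject lognormal multipliers
(log-SD 0.25) on the three sensitivities create between-subject spread
comparable to the published standard errors.

**Calibration.** The shipped defaults are: carbohydrate kernel peaking at
135 min (shape 4.2), protein/fat kernel at 250 min (shape 21), insulin
kernel at 196 min (shape 5.1); sensitivities 0.178 mmol/L per g
carbohydrate, 0.0166 mmol/L per kcal protein/fat, 2.36 mmol/L per insulin
unit. They were chosen, once, so that:

* the simulated NPM-CC cohort's mean peak lands near the published
  11.87 mmol/L. The cohort mean peak runs roughly 0.4 mmol/L above the
  noise-free mean-subject peak (taking a maximum over a noisy, heterogeneous
  ensemble is upward-biased), so the noise-free curve targets ~11.4;
* the high protein-fat meal peaks late (~240 min) under CC but early
  (~90-150 min) under FPU dosing, with the early/late lobes separated by at
  least ~0.75 mmol/L in each arm so the ordering survives sensor noise;
* all four noise-free 0-300 min arm means fall within 1 mmol/L of the
  published values.

Two structural facts about this model are worth recording. First, the
insulin-action kernel must peak *late* (we use 196 min): under linear
superposition, an insulin effect that decays after ~100 min removes more of
the early carbohydrate rise than of the late protein/fat rise, so a larger
bolus could only push the peak later — the opposite of the observed
time-to-peak reversal in the high protein-fat arms. A late kernel is
defensible as the cumulative glucose-lowering action of a bolus, which
accumulates well past the insulin-activity peak. Second, the published arm
summaries are not jointly reachable by any strictly dose-linear model: the
NPM arm pair implies roughly 3.6 mmol/L of mean-glucose lowering per extra
unit, the HPFM pair roughly 0.5. The calibration therefore prioritizes the
peak level and timing structure and accepts arm means within 1 mmol/L
rather than exactly.

**What passing simulation tests do and do not show.** The generator
reproduces timing, level and ordering statistics of the trial arms plus
crossover structure, heterogeneity, autocorrelated sensor noise and rescue
behaviour. It does not model gastric emptying, insulin-on-board, mixed-meal
interaction terms, sensor drift or dropout, or any within-subject covariance
beyond the shared profile; agreement on synthetic data validates the
*pipeline*, not the physiology of real patients.

## Crossover analysis

The unit of inference is the within-subject CC-minus-FPU difference, which
the crossover design supports directly; `compare_arms()` applies a paired
test per outcome. We deliberately use paired t and exact Wilcoxon
signed-rank tests rather than repeated-measures ANOVA or generalized linear
mixed models: with exactly two paired conditions per meal type these
collapse to the paired tests, and the mixed-model machinery is out of scope.
The signed-rank test drops zero differences, uses full enumeration of sign
assignments for up to 15 non-zero differences (exact even under ties), and a
tie-corrected, continuity-corrected normal approximation beyond. Binary
hypoglycemia outcomes use the exact discordant-pair binomial (McNemar)
test. No multiplicity correction is applied; the report prints the number
of comparisons so the reader can judge. Episode percentages are always
printed with their explicit denominator.

For context only: a two-sided 5% test with 80% power to detect a
2.5 mmol/L mean-glucose difference against a 2 mmol/L within-subject SD
needs 16 subjects per the usual paired formula; the package performs no
power machinery beyond this note.

## Problem sizes and numerical choices

The shipped tests run the simulator at n = 30 subjects (the trial's size)
for calibration checks and smaller n for structural checks; property suites
use 100 randomized traces/vectors per invariant. These sizes are the
package's own choice of a fast, convincing regression surface. Further
numerical conventions: half-up rounding (not banker's) wherever clinical
rounding is meant; dose-increment rounding after component summation;
trapezoid integration interpolates a non-grid right endpoint linearly;
`positive_only` iAUC interpolates baseline crossings within a segment;
random-number state is saved and restored around `simulate_trial()`, whose
output is a pure function of its configuration seed.

## Known limitations

* The simulator is phenomenological; its parameters are calibrated to
  arm-level summaries, not fitted to patient data.
* MAGE has several published variants; ours is the classical turning-point
  form. Values are comparable within this package, not necessarily across
  toolkits.
* Published AUC/iAUC table magnitudes of the source trial are internally
  inconsistent with the stated baseline-subtraction definition and are not
  used as numeric oracles anywhere.
* Time in range is reading-based; duration-based variants will differ
  slightly near range boundaries.
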