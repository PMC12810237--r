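---
title: "Methods: behavioral fingerprinting and identification refinement with vamrscreen"
author: "vamrscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral fingerprinting and identification refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vamrscreen)
```

## Scope

vamrscreen implements a desk-side version of an effect-directed analysis
(EDA) workflow for complex environmental mixtures such as crude-oil
water-accommodated fractions (WAF): larval zebrafish are exposed to a
mixture, its chromatographic fractions, or candidate single constituents;
their locomotor behavior under a visual/acoustic stimulus battery is reduced
to a 26-endpoint fingerprint; fingerprints are compared across treatments
and against a library of reference neuroactive compounds to generate
mode-of-action (MoA) hypotheses; and, on the chemistry side, tentative
GCxGC-MS identifications of fraction constituents are refined by
retention-plausibility filtering. The package covers the computational
pipeline only — video tracking, fractionation chemistry and spectral
deconvolution are upstream instruments whose tabular exports it consumes.

## The VAMR assay and its 26 endpoints

Video tracking quantifies per-larva locomotion as a per-frame activity
magnitude (delta pixel/s) at 25 frames/s. A stimulus schedule — typed,
timed segments — determines every endpoint window. The endpoints, in the
fixed order used everywhere in the package:

* **VSRB, VSR1, VSR2** — visual startle responses: mean activity over the
  1 s following the first three light-to-dark / dark-to-light transitions.
* **VMR1–VMR5** — visual motor responses: mean activity over the light
  phase (VMR1) and the four equal subdivisions of the dark phase
  (VMR2–VMR5).
* **BSL1–BSL4** — mean activity over the four scheduled baseline segments.
* **ASR1–ASR3** — acoustic startle responses: mean activity over the five
  concatenated 1 s tap windows of the low- (ASR1) and high-intensity
  (ASR2, ASR3) trains.
* **ISI1–ISI3, IEI1–IEI3, IBI** — summed activity over the inter-stimulus
  intervals within each train, the inter-endpoint intervals, and the
  intervals between habituation bouts.
* **ASH1** — within-bout habituation: activity of the final ten tap windows
  of the first 30-tap bout over the summed activity of its initial and
  final ten.
* **ASH1/5** — between-bout habituation: bout-5 total tap-window activity
  over the sum of bout-1 and bout-5 totals.
* **ASHsum** — total tap-window activity over all five bouts.
* **ASR2/3** — memory retention: ASR2 / (ASR2 + ASR3), computed per larva.

Conventions that make the numbers reproducible: times are seconds from
assay start with half-open windows `[start, end)`; a frame at timestamp
`(i-1)/25` belongs to a window if the timestamp falls inside it; mean
endpoints average per-frame values and sum endpoints add them (frame-sum
convention); remainder frames in a subdivision go to the final
subinterval; tap windows are `[tap, tap + 1 s)`. Ratio endpoints with zero
denominators are *missing*, not zero — a 0/0 ratio carries no information —
and missing values are dropped pairwise in group statistics.

Two definitional points were genuinely open and are resolved as follows,
configurable where it matters. ASR2/3 uses *per-larva* ASR2 and ASR3
values rather than cohort means, so that it has a per-larva distribution
like every other endpoint. VSRB is the response at the *first* scheduled
transition (the others follow in schedule order).

### The bundled schedule

Published assays of this family place their exact segment timings in
supplementary material; the bundled default (`default_schedule()`) is
therefore the package's own compact layout with the canonical structure:
dark baseline, light/dark alternation giving three visual transitions, a
low-intensity 5-tap train, a high-intensity 5-tap train, five 30-tap
habituation bouts with inter-bout intervals, and a final high-intensity
train after training (so ASR2 precedes and ASR3 follows habituation, as the
memory-retention endpoint requires), with four baselines and three
inter-endpoint intervals interleaved — 923 s in total. Short phases keep
simulation and testing fast without changing any endpoint definition; real
deployments load their own YAML schedule with `load_schedule()`, which
validates segment ordering, tap counts (5 per train, 30 per bout) and tap
placement, and derives the endpoint-window table.

## Effect statistics

For each treatment group and endpoint, the group is compared to its
designated control (solvent, blank-fraction, or medium control — the plate
map records which):

* **Effect size.** The strictly standardized mean difference,
  `SSMD = (mean_t − mean_c) / sqrt(var_t + var_c)` with unbiased
  variances: a variance-penalized effect size standard in high-throughput
  screening. It is antisymmetric, location-invariant, and already on a
  common scale across endpoints, which is why fingerprints need no further
  column scaling. Degenerate zero-variance comparisons with unequal means
  are capped at ±10 to keep downstream clustering finite. A median/MAD
  variant is available (`robust = TRUE`) for heavy-tailed cohorts.
* **Test.** A stratified bootstrap: cases are resampled within each arm,
  the statistic is the difference of medians (matching the median-centric
  way such assays are displayed), the bootstrap distribution is centered
  at the observed difference, and
  `p = (1 + #{|T* − T_obs| >= |T_obs|}) / (B + 1)` with `B = 1000` by
  default, so p is floored at `1/(B+1)`. Monte-Carlo calibration at
  n = 36/arm places the type-I error near 0.04 at alpha = 0.05 (the
  acceptance suite re-measures this on every run).
* **Multiplicity.** Benjamini–Hochberg across the 26 endpoints within each
  treatment, alpha = 0.05.
* **Direction.** Ternary calls: `none` unless the adjusted p-value is
  below alpha; otherwise the sign of the median difference (SSMD sign on
  median ties).

The bootstrap variant and adjustment method are explicit package choices —
workflows of this kind typically do not print theirs — and both are
parameters of `effect_table()`.

## Fingerprinting and MoA hypotheses

A treatment's fingerprint is its 26-vector of SSMDs. Fingerprints are
clustered jointly with a reference library (compound, concentration, MoA
annotation, 26 SSMD columns) by hierarchical clustering — Euclidean
distance and Ward linkage by default, correlation distance and average
linkage as the alternative — with a deterministic smallest-label-first
leaf order so dendrograms are reproducible across platforms. Missing
SSMDs (ratio endpoints with zero denominators) are imputed to 0 before
clustering and flagged. Flat clusters come from a height cut (default 40%
of the maximum merge height) or a fixed `k`.

`moa_report()` lists the MoA annotations of references co-clustered with a
query, ranked by membership count then minimum distance, falling back to
the 5 nearest references for singleton queries. The report is
hypothesis-generating only: cluster proximity suggests candidate targets
for pharmacological or genetic follow-up, nothing more. Absolute cluster
numberings are not comparable across distance/linkage choices and are not
treated as results.

The bundled reference library (`inst/extdata/synthetic_reference_library.csv`,
and `generate_reference_library()`) is *synthetic*: 63 rows built from
three MoA archetypes (disinhibition-like, sedative-like, stimulant-like)
plus Gaussian noise. Curated libraries of real reference compounds are
distributed with their own datasets; the synthetic stand-in reproduces
only their statistical shape so the clustering and reporting machinery is
fully testable.

## GCxGC-MS identification refinement

Deconvolution software emits peaks with a first-dimension retention time
(min), a second-dimension retention time (s within a 6 s modulation
period), an abundance, a tentative CAS identity and a spectral match
score. Refinement proceeds in four steps:

1. **Binning.** Peaks with identical CAS within a `[0.2 min, 0.2 s]`
   retention quadrant are split artifacts (tailing, modulation splits) and
   are merged. Linkage is transitive — connected components — and window
   comparisons are inclusive (`<=`, "within"), while the later filter
   thresholds are strict (`<`, "less than"). The merged peak is the
   abundance-weighted centroid with summed abundance and maximum match
   score, so binning conserves total abundance exactly.
2. **Retention indexing.** Van den Dool–Kratz linear interpolation against
   an n-alkane ladder: `RI = 100 n + 100 (t − t_n)/(t_{n+1} − t_n)`. No
   extrapolation beyond the ladder unless asked. Second-dimension times
   are first nulled against the baseline signal per modulation cycle
   (`baseline_align_rt2()`), interpolating sparse baseline observations
   along the first dimension.
3. **Retention prediction.** Two independent PLS regressions (via
   mixOmics) map 11 PubChem descriptors — molecular weight, xlogP, TPSA,
   complexity, atom stereo count, H-bond donor/acceptor counts, rotatable
   bond count, heavy atom count, defined/undefined stereo counts — to RI
   and to second-dimension time. The calibration set of 119 compounds is
   split 100 train / 19 test; the component count is chosen per response
   by seeded 10-fold cross-validation minimizing RMSE (at full rank PLS
   coincides with least squares, so a noiseless linear map is recovered to
   machine precision); held-out RMSE is reported for both responses.
   Constant descriptors are dropped with a warning. Models persist as
   versioned flat JSON in their equivalent linear intercept-plus-
   coefficients form, which predicts identically to the fitted object.
4. **Plausibility filter.** A tentative identity is kept only if match
   score > 80, |RI deviation| < 200 and |second-dimension deviation| < 2 s
   (all strict). Rejected rows carry every failing criterion; peaks
   without predictions are rejected as `no_prediction`. Retained and
   rejected rows always partition the input.

Composition summaries report per-fraction relative abundance (percent of
the fraction's retained total), per-class cumulative abundance and a
top-N table with alphabetical tie-breaks. Whether "abundance" is peak area
or height is irrelevant to the arithmetic; it is treated as an opaque
non-negative response. Unidentified peaks are excluded from
relative-abundance denominators by default (composition figures describe
identified constituents); this is configurable upstream of the summary by
leaving them in the retained table.

## Mixture and loading arithmetic

`waf_loading()` computes oil mass (volume x density) and the oil-to-water
loading rate; 32.2 uL of 0.75 g/mL oil over 240 mL gives ~24 mg and a
nominal 100 mg/L. `mixture_volumes()` converts component proportions of an
equal-molarity stock mixture into volumes and back
(`proportions_from_volumes()`, 1-decimal percents); combining any volumes
of 20 mM stocks stays 20 mM. `dilution_series()` builds constant-factor
series; the quarter-log preset uses `10^0.25`. Six quarter-log steps down
from 80 uM give 80, 45.0, 25.3, 14.2, 8.00, 4.50 (3 significant figures);
protocols sometimes print 4.4 for the low end, a value a constant
quarter-log factor cannot produce — published series that do not follow
one constant factor should be entered verbatim rather than generated.
Fixed rounding conventions (nearest mg for mass, 2 significant figures for
loading, 1 decimal for percents, 3 significant figures for
concentrations) exist so printed protocol values are reproduced exactly.

## The synthetic-data generators

`generate_plate()` emulates the statistical structure the behavioral
stages assume: per-frame activity is multiplicative-lognormal background
(`baseline_level x phase multiplier x per-larva lognormal scale x
per-frame lognormal noise`) plus stimulus-locked 1 s boxcar pulses. Tap
responses decay within a bout as `exp(-lambda (tap − 1))` and carry a
between-bout factor `pot^(bout − 1)` modeling recovery/potentiation
between training bouts. Treatment wells multiply family-specific levels
(baseline/light/dark background, visual pulses, acoustic pulses, the decay
rate lambda); these multipliers are the injected ground truth the effect
table is asked to recover. The truth table records first-order effects
only: an acoustic amplitude multiplier leaves the decay rate untouched but
raises the pulse-to-background ratio inside tap windows, which can itself
shift the habituation ratios — visible in practice as ASH1/ASH1/5 calls
accompanying strong acoustic effects.

Modeling choices, stated as such: lognormal noise because locomotor
activity is non-negative and right-skewed; a per-larva lognormal scale
factor (`larva_sigma = 0.3`) because real cohorts vary between animals —
without it, within-larva averaging would make every effect size diverge
and recovery tests would be meaningless; boxcar pulses because endpoint
windows integrate them exactly. Defaults (`n_per_group = 36`, within the
36–72 range typical of these assays; baseline 2 delta pixel/s; dark
multiplier 2; lambda 0.12; pot 0.75) were fixed once as plausible
field-scale values and are not tuned. What the generator does *not*
emulate: swim kinematics, plate-edge and batch effects, temporal
autocorrelation beyond the pulse structure, mortality dynamics. Passing
recovery tests therefore demonstrates the statistical machinery is
correct and well calibrated under the assumed data structure, not that any
particular real-world effect will replicate.

`generate_peaklist()` draws descriptors uniformly over realistic ranges
and places true compounds by a fixed linear descriptor-to-retention map
(kept inside a C8–C30 ladder and a 6 s modulation period) plus Gaussian
noise (`sigma_RI = 30`, `sigma_rt2 = 0.3 s` by default); decoys keep a
real identity but draw retention uniformly, so their retention rate under
the filter equals the analytic window-overlap probability — a property the
test suite checks. `generate_retention_calibration()` produces the
119-compound calibration table from the same map.

## Problem sizes and runtime choices

The validation suite runs on one CPU with deliberately chosen sizes:
endpoint-oracle equivalence on 3 random full-length traces (exact to
1e-12); ASH1 -> 0.5 on 200 simulated larvae (tolerance 0.02); bootstrap
type-I error over 1000 null simulations at n = 36/arm, B = 199 (band
0.03–0.07); effect recovery over 100 seeded plates at n = 36/arm with
B = 200 (sensitivity >= 90% on endpoints injected at |SSMD| >= 1);
PLS recovery on the 100/19 split; filter retention on 300 true peaks;
archetype clustering on 63 references with 10 noisy queries. `B = 1000`
remains the analysis default; the smaller `B` in simulation loops only
coarsens the p-value grid, which the direction-call threshold tolerates.

## Known limitations

* Direction calls use the median difference while SSMD uses means; on
  strongly skewed bimodal data the two can disagree in sign. The package
  calls direction from the median (consistent with its test statistic)
  and reports SSMD alongside, so disagreement is visible, not hidden.
* The bootstrap is slightly conservative at these sample sizes (~0.04
  rejection at alpha = 0.05).
* SSMD caps at ±10 flatten genuinely infinite effects; they occur only
  for zero-variance endpoints.
* Cluster identities depend on distance/linkage; only co-membership and
  nearest-reference structure should be interpreted.
* The retention filter inherits the calibration model's bias outside the
  descriptor ranges it was trained on; extrapolated predictions are not
  flagged.
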