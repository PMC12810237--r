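# vamrscreen

Behavioral fingerprinting and effect-directed chemical analysis for larval
zebrafish screens.

## What it is for

Effect-directed analysis (EDA) localizes the chemical drivers of a complex
environmental mixture's biological effect — for example a crude-oil
water-accommodated fraction (WAF) — by fractionating the mixture,
bioassaying the fractions, and chemically characterizing the active ones.
`vamrscreen` implements the computational arm of such a workflow around the
larval zebrafish **visual and acoustic motor response (VAMR) assay**:

* **Behavior:** read per-larva locomotor activity traces (delta pixel/s at
  25 frames/s) with a plate map and a stimulus schedule, apply viability
  exclusions (dead / malformed / uninflated swim bladder / tracking gaps),
  and reduce each larva to **26 named endpoints** (visual startle and motor
  responses, baselines, acoustic startle, interval activity, habituation
  and memory-retention ratios).
* **Statistics:** per endpoint and treatment group, the strictly
  standardized mean difference against the designated control,

  `SSMD = (mean_t − mean_c) / sqrt(var_t + var_c)`,

  a stratified bootstrap test on the difference of medians,
  Benjamini–Hochberg adjustment across the 26 endpoints within each
  treatment, and ternary increase/decrease/none calls.
* **Mode-of-action fingerprinting:** hierarchical clustering of treatment
  SSMD fingerprints with a reference library of neuroactive compounds of
  known target; ranked, hypothesis-generating MoA reports from cluster
  co-membership and nearest references.
* **Chemistry:** GCxGC-MS identification refinement — retention-quadrant
  binning of split peaks, van den Dool–Kratz retention indices against an
  n-alkane ladder, PLS prediction of retention from 11 physicochemical
  descriptors (119-compound calibration, 100/19 train/test), and the
  plausibility filter *match score > 80, |ΔRI| < 200, |Δrt2| < 2 s*,
  followed by composition summaries.
* **Mixture arithmetic:** WAF loading rates, proportional mixtures of
  equal-molarity stocks, quarter-log dilution series.
* **Synthetic data:** seeded generators for traces, peak lists and
  reference libraries with known ground truth, so the whole pipeline is
  testable end to end without any instrument data.

See `vignettes/vamrscreen-methods.Rmd` for the full model description and
the reasoning behind every numerical convention.

## Worked example

Simulate a 36-larvae-per-arm plate whose treatment halves dark-phase
activity and doubles acoustic startle, extract endpoints, and test every
endpoint against the control arm:

```r
library(vamrscreen)

sch   <- default_schedule()
cfg   <- trace_config(seed = 7, n_per_group = 36,
                      treatment = list(dark = 0.5, acoustic = 2))
plate <- generate_plate(cfg, sch)
ep    <- compute_endpoint_matrix(plate$traces, sch)
eff   <- effect_table(ep, plate$plate_map, B = 1000, seed = 7)
subset(eff$effects, direction != "none",
       select = c(endpoint, ssmd, p_adj, direction))
#>  endpoint   ssmd  p_adj direction
#>      VMR2 -1.339 0.0026  decrease
#>      VMR3 -1.535 0.0026  decrease
#>      VMR4 -1.554 0.0026  decrease
#>      VMR5 -1.538 0.0026  decrease
#>      ASR1  0.958 0.0026  increase
#>      ASR2  1.080 0.0026  increase
#>      ASR3  1.238 0.0026  increase
#>      ASH1 -1.970 0.0026  decrease
#>    ASH1/5 -1.644 0.0026  decrease
#>    ASHsum  1.124 0.0026  increase
```

The four dark-phase endpoints are called *decrease* and the acoustic
endpoints *increase*, recovering the injected effects (the habituation
ratios also drop because stronger pulses raise the pulse-to-background
ratio inside tap windows). Clustering the treatment fingerprint against
the bundled synthetic reference library names the archetype it resembles:

```r
lib <- read_reference_library(system.file("extdata",
         "synthetic_reference_library.csv", package = "vamrscreen"))
cl  <- cluster_fingerprints(eff, lib)
moa_report(cl, "treatment")
#> MoA hypotheses for 'treatment' (cluster 1, basis: co-cluster)
#>  moa_class  n min_distance
#>  stimulant 21     6.676076
#> Hypothesis-generating only; requires pharmacological or genetic follow-up.
```

Mixture arithmetic reproduces protocol values exactly:

```r
waf_loading(32.2, 0.75, 240)[c("oil_mass_mg_rounded", "loading_rounded")]
#> $oil_mass_mg_rounded  [1] 24
#> $loading_rounded      [1] 100
proportions_from_volumes(c(331.9, 96.8, 71.3))
#> [1] 66.4 19.4 14.3
dilution_series(80, n = 6)
#> 6-step dilution series (factor 1.778): 80, 45, 25.3, 14.2, 8, 4.5 uM
```

A thin command-line front end with `simulate` / `behavior` / `chemistry` /
`fingerprint` / `mixture` subcommands lives at
`inst/cli/vamrscreen-cli.R`; the exported functions `run_behavior()` and
`run_chemistry()` drive whole config-file runs with JSON manifests.

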