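# rnptransport

Quantitative analysis of single-molecule TIRF assays of minus-end-directed
mRNA transport on microtubules — the reconstituted dynein–dynactin /
BicD-adaptor / Egl / localisation-signal-RNA system — for researchers who
score kymograph tracks and count fluorophores rather than fit structures.

The package implements two things end to end:

1. **Motility quantification.** Digitised particle tracks (time, position
   along a microtubule; minus end at coordinate 0) are scored as binding
   events if they last ≥ 3 frames (1.5 s at 2 frames/s) and classified as
   *processive* (net minus-end displacement ≥ 0.5 µm with directionality
   |net|/path ≥ 0.7), *static* (excursion within the localisation-noise
   envelope) or *diffusive* (the rest). Processive events get
   piecewise-constant velocity segments (penalised least-squares
   changepoint fit, exact DP optimum), censored run lengths (runs kept only
   if fully observed or starting > 5 µm from the minus end), a one-phase
   exponential survival fit `1 − CDF(x) = exp(−x/λ)`, per-microtubule
   counts corrected for coverslip background, and two-colour co-transport
   fractions.
2. **Copy-number stoichiometry.** Closed-form dual-fluorophore labelling
   models: binomial SNAP labelling of a *k*-copy complex,
   `P(dual) = 1 − (1−pq)^k − (1−p(1−q))^k + (1−p)^k`, and Poisson
   body-labelled RNA with detection probability `L = 1 − e^{−mean}`. Their
   inversions turn an observed dual-colour fraction of motile complexes
   into the mixture of one- vs two-copy complexes, with bootstrap or
   Wilson confidence intervals. At the assay's calibration (90% SNAP
   labelling, equal dye split) an obligate dimer shows 40% dual complexes
   (50/25/25 at full labelling, 81% of dimers carrying two dyes), and an
   observed 14% dual-RNA fraction at ~3 dyes per RNA inverts to a 30/70
   two-RNA/one-RNA mixture.

A synthetic-data module (`simulate_trackset()`, `simulate_dual_labels()`,
`simulate_rna_labels()`, `render_kymograph()`) generates trajectories and
labelling outcomes with known ground truth, so the whole pipeline runs and
is tested at desk scale with no imaging data.

## Worked example

```r
library(rnptransport)

# simulate a field of microtubules with a known motility mixture
cfg <- sim_config(n_microtubules = 10, tracks_per_mt_mean = 18,
                  class_probs = c(static = 0.35, diffusive = 0.25,
                                  processive = 0.40), seed = 42)
ts  <- simulate_trackset(cfg)
mot <- classify_tracks(ts)
print(mot)
#> <motility_result> 155 binding events (38 tracks rejected)
#>  diffusive processive     static
#>         38         51         66

fit_decay(extract_run_lengths(mot))
#> <decay_fit> 1-CDF ~ exp(-x / 4.42 um), n = 43 runs, domain 0.67-14.10 um

# copy number: 39% of motile complexes showed both dyes at 90% labelling
infer_two_copy_fraction(dual_colour_counts(390, 305, 305),
                        p_label = 0.9, q_dyeA = 0.5)
#> <copy_number_estimate> two-copy 94.9% / one-copy 5.1%  (95% CI 86.7-100.0%, bootstrap, n = 1000)

# RNA: 14% dual-colour RNPs at ~3 dyes per molecule
infer_rna_mixture(dual_colour_counts(140, 430, 430), poisson_mean = 3)
#> <copy_number_estimate> two-copy 29.9% / one-copy 70.1%  (95% CI 25.6-34.7%, bootstrap, n = 1000)
```

The survival-fit scale (4.42 µm here) estimates the mean run length of the
processive population after censoring; the copy-number estimates read as
"95% of motile complexes carry two BicD-adaptor copies" and "30% of motile
RNPs carry two RNA molecules".

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate_tracks.R` → `04_copy_number.R`), each writing its tables
under `results/`. A ready-made pipeline configuration is bundled at
`inst/extdata/demo_run.yaml` (`run_pipeline(load_run_config(...))`), and
`inst/extdata/demo_dual_counts_synthetic.tsv` carries dual-colour counts
constructed from the published percentages (synthetic, not raw data).

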