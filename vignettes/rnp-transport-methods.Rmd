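---
title: "Methods: motility classification and copy-number inference for reconstituted mRNA transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motility classification and copy-number inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnptransport)
```

# Scope

`rnptransport` quantifies single-molecule TIRF motility assays of
minus-end-directed mRNA transport complexes (dynein–dynactin activated by the
BicD-family adaptor loaded with Egl and a localisation-signal RNA). It covers
the two computational halves of such an experiment:

1. **Motility**: classifying kymograph-derived particle tracks into static,
   diffusive and processive binding events; segmental velocities; censored
   run lengths with a survival-curve fit; background-corrected event counts;
   two-colour co-transport.
2. **Stoichiometry**: closed-form dual-fluorophore labelling models and
   their inversions, which convert observed dual-colour fractions of motile
   complexes into one- versus two-copy mixtures.

A synthetic-data generator produces trajectories and labelling outcomes with
known ground truth, so every stage can be tested for parameter recovery
without any imaging data. All analyses operate on digitised tracks (tables
of time and position along a microtubule); spot detection and tracking from
raw movies are out of scope.

# The track model and what the generator emulates

Coordinates are positions (µm) along a microtubule whose **minus end sits at
0**; minus-end-directed transport therefore means a *decreasing* coordinate,
and signed displacements are negative for minus-end travel. Movies are point
samples at a fixed frame interval (default 0.5 s, i.e. 2 frames/s) with
105 nm pixels; exposure-time motion blur is not modelled.

`simulate_trackset()` draws, per microtubule (length normal, default
14 ± 3 µm, truncated at 1 µm), a Poisson number of tracks. Each track
attaches at a uniform random time and position and belongs to one of three
classes:

* **static** — fixed position, localisation noise only; detaches after an
  exponential attachment duration (default mean 6 s, comparable to the
  ~5 s mean processive event so that the event-duration distributions of
  the classes are commensurate);
* **diffusive** — unbiased Gaussian random walk (default
  D = 0.05 µm²/s), reflected at the microtubule ends, same detachment;
* **processive** — piecewise-constant velocity toward the minus end.
  Per-segment speeds are drawn from a normal (default 1.0 ± 0.25 µm/s)
  truncated at zero — the assay reports segmental velocity distributions
  but no generative family, so a simple truncated normal is used for
  testability — with new segments at an exponential switching rate
  (default 0.1 s⁻¹). The particle detaches once its exponentially
  distributed run length (default mean 5 µm) is exhausted, or arrests on
  reaching the minus end, where it persists for the remainder of the movie
  (minus-end accumulation). Run length governs processive detachment
  instead of the attachment clock; a time cap would destroy the exponential
  run-length distribution that the run-length statistics rely on.

Every sampled position receives Gaussian localisation noise (default
0.05 µm) and is clipped to the microtubule. Ground truth (class, drawn run
length, segment velocities, arrest status) is recorded per track, and the
whole generator is deterministic given the seed.

**Not emulated**: photobleaching and blinking, off-axis (2-D) motion,
crossing-track ambiguity, point-spread-function shape beyond a Gaussian
spot in the kymograph renderer, uneven illumination, and any correlation
between channels beyond what the user constructs. Tests passing on these
synthetic data therefore validate the *estimators* under the stated
stochastic model, not robustness to every artefact of real movies.

# Event classification

Tracks shorter than `min_frames` (3) frames or `min_duration` (1.5 s) are
not binding events and are rejected. Duration is counted as
`n_frames × frame_interval`, so at 2 frames/s the two thresholds coincide
(three frames ↔ 1.5 s). Accepted tracks are classified by two interpretable
statistics: the signed net displacement *N* toward the minus end and the
path length *P* (sum of absolute frame-to-frame displacements):

* **processive** if the net minus-end displacement is at least
  `processive_min_net` (0.5 µm, five pixels) *and* the directionality ratio
  |N|/P is at least `directionality_min` (0.7, the operationalisation of
  "predominantly directed without significant diffusive behaviour");
* otherwise **static** if the maximum excursion from the mean position is at
  most `static_max_excursion` (default `2·localisation_sd·√2`);
* otherwise **diffusive**.

One subtlety matters in practice: a processive particle that arrests at the
minus end and then sits there accumulates localisation-noise path length
while gaining no displacement, which would eventually push |N|/P below any
threshold. Scoring by eye does not suffer from this, so before computing
*N* and *P* the classifier trims the terminal dwell — frames after the
track has entered, and never again left, a `minus_end_zone` (0.2 µm) around
the minus end. The arrival frame is kept, the arrest is flagged
(`arrived_minus_end`), and the event is marked censored. The same 0.2 µm
zone defines "not end-arrested" for run-length eligibility below. All
thresholds are exposed in `classify_params()`.

Classification is deterministic and invariant to uniform time shifts and to
reflecting the coordinate axis together with the minus-end convention
(verified as properties in the test suite).

# Segmental velocities

Motile complexes change speed mid-run, so velocities are reported per
constant-velocity segment. `segment_velocities()` minimises
`sum RSS(segment) + β·(number of segments)` over all partitions into
segments of at least `min_segment_frames` (3) points, by dynamic
programming with O(1) per-segment least-squares costs — an exact search,
so for single-changepoint tracks it provably matches a brute-force
single-breakpoint scan. The penalty is
`β = changepoint_penalty · σ̂² · log n`, with σ̂ estimated robustly from
second differences (which annihilate any piecewise-linear trend). An
infinitesimal floor on β resolves ties toward fewer segments, which makes
noiseless piecewise-linear tracks segment *exactly*. The default
`changepoint_penalty = 10` was calibrated on simulated two-segment tracks
against the brute-force oracle (50 nm noise, velocity steps ≥ 0.4 µm/s):
≥ 90% of changepoints are recovered within ±2 frames. Adjacent segments
with velocities closer than `velocity_merge_tol` (0.1 µm/s) are merged;
segments slower than `pause_velocity_max` (0.05 µm/s) are flagged as pauses
and excluded from velocity distributions while still counting toward run
length.

# Run lengths, censoring, and the survival fit

Run length is the magnitude of a processive event's total displacement,
pauses and velocity changes included. Runs are kept for statistics only if
the entire run was observed (appeared after the movie start, disappeared
before its end, not end-arrested) or if they began more than 5 µm from the
minus end; everything else is discarded as badly censored. On simulated
exponential runs (mean 5 µm) on 20 µm microtubules this rule reduces the
truncation bias of the mean from about −25% to −18% (both values match a
closed-form oracle integrated over the start-position distribution); it
mitigates, but cannot eliminate, minus-end censoring.

`fit_decay()` fits `1 − CDF(x) = exp(−x/scale)` to the empirical survival
curve by least squares (`stats::optimize` on the single scale parameter).
The fit is a presentation device, as is conventional for run-length data;
`compare_conditions()` (Student, Welch or Mann–Whitney via the standard
`stats` routines) always operates on raw values. Degenerate inputs (all
runs identical) still return a positive scale but carry a
`poorly_conditioned` flag; fewer than 10 runs is an error.

# Event counts and background

Non-specific binding to the coverslip inflates per-microtubule counts.
`count_events()` subtracts the mean count of microtubule-free regions
sampled at the median microtubule length, scaled linearly to each
microtubule's length (the linear scaling generalises equal-length regions
with the same expectation), flooring at zero. Simulation tests confirm the
corrected counts are unbiased for the true microtubule-specific counts.

# Two-colour co-transport

`colocalize()` pairs tracks across channels on the same microtubule: a pair
co-localises if their positions agree within `max_gap` (0.21 µm, two
pixels) for at least `min_overlap_fraction` (0.5) of the shorter track's
frames. Both thresholds are exposed because the underlying judgement is
inherently manual; the defaults recover a planted 75% co-transport fraction
within binomial sampling error in the test suite.

# Copy-number stoichiometry

Two labelling chemistries give two closed-form models.

**Binomial SNAP labelling** (`dual_label_distribution()`): each of *k*
polypeptides carries a dye with probability *p* and a carried dye is
species A with probability *q*. By independence,

$$P(\text{dual}) = 1 - (1-pq)^k - (1-p(1-q))^k + (1-p)^k.$$

For an obligate dimer this yields the 50/25/25 dual/A-only/B-only split at
full labelling, 0.405 (40%) dual at the measured *p* = 0.9, and
`both_labeled_fraction(2, 0.9)` = 81% of dimers carrying two dyes.
`infer_two_copy_fraction()` inverts the detected-conditional mixture
$$d = \frac{\varphi\,\mathrm{dual}_2}{\varphi\,\mathrm{det}_2 + (1-\varphi)\,\mathrm{det}_1}$$
for the two-copy weight φ, clipping to [0, 1] and flagging observations
above the φ = 1 ceiling as out-of-model.

**Poisson body-labelled RNA** (`rna_dual_fraction()`): each RNA carries a
Poisson number of dyes (mean ~3 from the transcription protocol), so it is
detected with probability `L = 1 − exp(−mean)` ≈ 0.95, and each RNA comes
from the colour-A preparation with probability *a* (0.5 for equimolar
mixes). Among *detected* RNPs the dual fraction of a mixture with two-RNA
weight f₂ is

$$d = \frac{f_2\,2a(1-a)L^2}{(1-f_2)L + f_2\,(1-(1-L)^2)},$$

with the closed-form inverse `f₂ = dB/(A − d(C−B))`, `A = 2a(1−a)L²`,
`B = L`, `C = 1−(1−L)²`. An observed 14% dual fraction at mean 3 dyes and
equimolar colours inverts to f₂ ≈ 0.30 — a 30/70 two-RNA/one-RNA mixture.
Two same-colour RNAs are assumed to be scored single-colour (intensity is
not used). Observed fractions are always conditioned on detection because
undetected complexes are invisible in the assay; the unconditional dual
probability is also exposed (`expected_dual_fraction()`), since the 40%
dimer figure is conventionally quoted unconditionally.

Confidence intervals: a seeded nonparametric bootstrap over detected
complexes (default 1000 resamples, percentile interval) on the dual
fraction, propagated through the monotone inversion; a Wilson score
interval is available as a closed-form alternative. Internally everything
is kept at full precision; only report layers round to whole percent.
Copy-number support is restricted to mixtures of one and two copies —
the dimeric-adaptor framework this assay was built around; the forward
enumeration accepts any *k*, but mixtures beyond two components are out of
scope.

# Numerical and design choices

* Exact closed forms are used wherever enumeration admits them; the
  Monte-Carlo simulators exist to *check* those forms (agreement within
  4 binomial SE at n = 10⁵ is asserted in the tests), never to replace
  them.
* Ties in the changepoint search resolve to fewer segments; the infinite
  penalty floor is 10⁻¹², far below any data-driven cost.
* Division guards: conditioning on detection with `p_label = 0` and the
  RNA model with `poisson_mean = 0` return `NA` with a warning rather than
  dividing by zero; inversion denominators at or below zero return the
  φ = 1 boundary with the out-of-model flag.
* The dye split *q* defaults to 0.5 but is a parameter, since real dye
  batches need empirical balancing; all probability parameters are
  validated into [0, 1] with errors naming the offending field.
* Serialisation writes doubles at 17 significant digits, so a track-table
  round trip is bit-lossless.

# Problem sizes

The test suite and the reproduction script run at desk scale: labelling
Monte-Carlo at 10⁴–10⁵ complexes, track sets of roughly 200–500 tracks on
10–25 microtubules, 200 tracks for changepoint-recovery and co-transport
studies, 1000 runs for the survival-fit recovery, 1000 replicates for the
Welch size calibration, and 50 repeat experiments of 300 complexes for
copy-number recovery. These sizes were chosen to keep every Monte-Carlo
assertion's sampling error a few times smaller than the tolerance it
checks.

# Known limitations

* The classified processive *fraction* is a slightly biased estimator of
  the generating class probabilities: particles that land within a fraction
  of a micron of the minus end arrest before achieving measurable
  displacement and are (correctly) scored static, and short runs fall
  under the three-frame minimum. Under the default conditions this
  depresses the classified processive fraction by roughly 3–4 percentage
  points relative to the landing probabilities. This is a property of the
  scoring protocol itself, not of the implementation.
* The censoring rule reduces, but does not remove, minus-end truncation
  bias in run lengths; fitted scales should be compared between conditions
  measured on the same geometry.
* Whether diffusive episodes flanking a processive run should be trimmed
  before measuring run length is left as scored: the event's total
  displacement is used.
* The generator's attachment-duration, pause and minus-end-dwell
  distributions are modelling choices, not measured quantities; conclusions
  that depend on them should be checked for sensitivity.
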