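---
title: "Testing sensor-space signals against the axioms of reward prediction error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing sensor-space signals against the axioms of reward prediction error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(axiomerf)
```

## The model being tested

A reward prediction error (RPE) integrates the value of an outcome with its
prior probability: it is positive for better-than-expected events, negative
for worse-than-expected ones, largest in magnitude for unlikely outcomes,
and zero when the outcome was fully anticipated.  On a gambling design with
outcome valence (win, loss) crossed with realized-outcome probability
(.25, .50, .75, 1), any signal `S` expressing an RPE must satisfy three
axioms: (1) wins and losses differ for uncertain outcomes; (2) `S` is
modulated by probability *within both* valences, with slopes that are
nonzero, different from each other, and opposite in sign; (3) fully
anticipated (P = 1) wins and losses are equivalent.  Axiom 2 is the
discriminating one: a signal whose win and loss amplitudes drift with
probability in the *same* direction — as the scalp-potential average
around the FRN window does — expresses expectancy or salience, not a
bidirectional teaching signal.

The package operationalizes the battery exactly as a sensor-space
mass-univariate analysis would: condition-mean amplitudes per subject on
the 2 × 4 grid, a repeated-measures ANOVA with subject as the random
factor (uncorrected degrees of freedom by default; Greenhouse–Geisser
adjusted p-values are available via `gg_correction`, and a Holm option
covers the paired-test families, both off by default to match
conventional uncorrected reporting), per-subject
probability slopes obtained by least squares against P, paired t tests
for the valence ordering at each probability and for the P = 1
equivalence, and a linear polynomial trend on the win − loss difference.
The overall grade is `compliant` when all three axioms pass and at least
one adjacent-probability step of the valence difference is individually
significant; `weakly_compliant` when the interaction, sign-opposition and
P = 1 criteria hold but some individual sub-test does not (the
conventional description of partially graded empirical patterns); and
`violated` otherwise.  Because axiom 3 asserts a null, the default test
is absence of a significant difference at a *lenient* threshold, with an
optional two-one-sided equivalence test (`equivalence_bound`) for users
who want a positive statement; a null result alone cannot prove
equivalence.

## What the synthetic sessions emulate

`build_session_design()` reproduces the 540-trial session: 45 gambles at
win probability 0 and at 1, 90 at .50, 180 at .25 and at .75, in 9 blocks
of 60 with equal per-probability counts per block.  Outcomes are realized
by exact stratified assignment — at win probability P with N gambles,
exactly N·P wins — so realized frequencies match nominal probabilities in
every single session; an i.i.d. Bernoulli mode exists for comparison.
Conditions are labelled by the probability of the *realized* outcome
(a loss after a .25-win gamble is a P = .75 loss), which is why the two
P = .75 cells collect 135 outcomes while all others collect 45, and why
"45 at 0 or 1 win probability" is read as 45 at each (the only reading
summing to 540).  Lure gambles, choices and reaction times are not
simulated: every analysis here is outcome-locked.

`simulate_evoked()` builds each trial as a superposition of components,
each a Gaussian time course × a fixed sensor topography × a gain
`g(valence, P)`:

* a valence component at 200 ms (gain ±1, probability-independent);
* a probability component at 340 ms (gain `1 − P`, identical for both
  valences — a P300-like expectancy response);
* the prediction-error component at 320 ms (gain `±β(1−P)`, exactly zero
  at P = 1).

Topographies are ideal dipolar fields: the radial magnetic field of a
current-dipole element inside the head sphere, sampled at 275 axial
gradiometers laid out on a Fibonacci spiral over a 110° cap of an 11 cm
helmet sphere (a quasi-uniform whole-head array without the cocircular
degeneracies of latitude grids).  Amplitudes are set to realistic evoked
scales (≈ 0.8–1.1 × 10⁻¹³ T at the peak for unit gain).  Noise is white
plus `1/f^α` (α = 1 by default), generated in one spectral synthesis
(the sum of independent Gaussian fields is a Gaussian field with summed
spectra) with single-trial SD 5 × 10⁻¹³ T per floor — a few times the
evoked scale, as in real recordings.  Eye blinks add a rank-1 spatial
pattern (proximity falloff from the eyes) with a stereotyped Gaussian
time course at ~8% of trials and 4 pT amplitude; channel jumps add
sustained baseline steps (SQUID-jump-like) of 5 × 10⁻¹⁰ T at 1% of
trials, which survive band-pass filtering and are what the amplitude
rejection stage is meant to catch.  Between-subject variability is a
lognormal gain with SD 0.1.

What these simulations deliberately do **not** contain: realistic
anatomy or forward modelling, correlated multi-source background
activity, non-stationary noise, eye movements other than blinks, or any
trial-history structure.  Passing the recovery suite therefore shows the
*analysis chain* is correct and calibrated — not that real data of this
SNR would behave as cleanly.

## Preprocessing

The driver enforces the canonical order: resample (600 → 200 Hz, with an
anti-alias zero-phase low-pass at 0.45 × the target rate), band-pass
0.5–30 Hz, baseline correction over t < 0, amplitude rejection at
1.5 × 10⁻¹⁰ T, blink projection, condition averaging.  Filters are
fourth-order Butterworth designs applied forward–backward (zero phase),
realized as a high-pass/low-pass cascade, with odd-reflection padding and
steady-state initial conditions; the compiled kernel processes all
trial × channel series of an epoch array at once.  On an 860 ms epoch a
0.5 Hz high-pass is necessarily imperfect near the edges — the filter's
transient is longer than the epoch — so unit tests validate the
magnitude response on long probe signals, and the pipeline relies on the
fact that the operation is *linear*: every condition and gain level is
transformed identically, leaving contrasts and slope ratios intact.

Blink projection follows signal-space projection: blinks are detected as
|z| > 4 excursions (≥ 200 ms apart) on the most eye-proximal channel,
the data are averaged around the detected events, and the top k = 4
spatial principal components of that blink-locked average are removed by
the orthogonal projector `I − BBᵀ`.  Rejection runs before projection.

Robust averaging computes, per channel and time point, an iteratively
reweighted mean of MAD-scaled residuals.  The weight function is Tukey's
redescending bisquare with cutoff 15 MAD-scaled SDs (Huber weights are
available as an option).  The cutoff was chosen from the two requirements
the averager must satisfy simultaneously: on clean Gaussian data the
robust and arithmetic means should agree to a small fraction of the SEM
(at cutoff 15 the difference has SD ≈ 0.02 SEM at 45–50 trials; at the
classic 95%-efficiency constants it is ≈ 0.2 SEM, i.e. the estimator
visibly departs from the mean on artifact-free data), while gross bursts
(≳ 10 SD) must be effectively excluded (a redescending function assigns
them near-zero weight; a Huber function with a large constant would not).
Iteration runs to a relative tolerance of 10⁻⁶ or 50 iterations
(weight-switching limit cycles occasionally prevent formal convergence;
the last iterate is returned with a warning).  Zero-MAD columns fall
back to the mean-absolute-deviation scale.  Averages are low-pass
filtered at 30 Hz afterwards, as the weighting can introduce high
frequencies.  MEG condition averages use plain arithmetic means by
default; robust averaging is the default for the EEG arm.

## Scalp images and the group model

Sensor positions are projected azimuthally-equidistantly about the
vertex.  A whole-head array spans ≈ ±170 mm in that projection, which
cannot sit inside a 64-pixel grid of 3 mm pixels, so projected radii are
rescaled once per layout so the outermost sensor lies at 90 mm — the
same fit-to-grid step any fixed-grid imaging pipeline applies; reported
peak coordinates are in the rescaled mm frame, with the factor stored
alongside the projection.  Images are built by piecewise-linear
(Delaunay/barycentric) interpolation with sensors as vertices — exact
for constant and affine sensor fields, the defining property checked in
the tests — with pixels outside the sensor hull marked invalid rather
than extrapolated.  Smoothing is a separable Gaussian of FWHM
8 mm × 8 mm × 8 ms, renormalized over valid pixels at the hull boundary
(so constants are preserved), and statistics are restricted to
100–600 ms.

The group model is a per-voxel OLS ANCOVA: win and loss indicators,
probability modulators coded 4, 3, 2, 1 for P = .25…1 and mean-centred
within their condition rows, and treatment-coded subject block
regressors (a pooled model without subject effects is available).
F statistics use the standard extra-sum-of-squares form; the critical
value is computed from the model's own residual degrees of freedom
rather than hard-coding any published threshold, because a non-sphericity
adjusted df cannot be recovered from a printed F alone.  Suprathreshold
voxels (peak p < 0.005) are grouped by 26-connectivity in (x, y, t),
clusters under 100 voxels are dropped, and peak Z-equivalents map the
F's upper-tail probability through the standard normal quantile.  The
critical interaction contrast is additionally restricted by an inclusive
mask: a voxelwise paired F test of win vs loss at P = 1 at a *lenient*
α = 0.05, inverted, so that the analysis only reports locations where
fully predicted outcomes did not differ.

A known limitation, documented deliberately: cluster-extent thresholds
at this smoothness do not control family-wise error (random-field or
permutation corrections are out of scope here), so occasional
false-positive clusters above 100 voxels appear even under a null
simulation; the calibration that *is* guaranteed — and verified by the
null suite — is the voxel-level false-positive fraction at α and the
exclusion rate of the equivalence mask.

## Numerical and design choices

* Epochs are sampled on `t ∈ [−160, 700)` ms, half-open on the right;
  baseline is `t < 0`.  At 200 Hz the 100–600 ms mask keeps 101 frames.
* The triangulation adds a deterministic sub-micrometre jitter before
  Bowyer–Watson insertion to guard against exactly cocircular quadruples;
  the induced interpolation error is ~10⁻⁷ relative.
* FRN extraction takes the *earliest* minimum on ties.  Note that
  minimum extraction is negatively biased by noise (the minimum of a
  noisy null difference wave is below zero by ≈ 2–2.5 noise SDs), and
  the bias differs between 45- and 135-trial cells; group inference on
  the minima is still valid, but raw mean minima should not be read as
  unbiased amplitude estimates.
* The EEG arm is calibrated against the qualitative anchors reported for
  scalp-potential studies of this design: a difference-wave FRN of
  ≈ −5 µV at P = .25 shrinking toward zero at P = 1.  That fixes the
  FRN-like component at 7 µV (for unit gain; gains 0.5–3.5 across
  cells, equal for wins and losses at P = 1) and single-trial noise
  floors of 8 µV white + 8 µV 1/f — a clean laboratory recording.  Both
  valences scale *positively* with probability (win `2 + 1.5P`, loss
  `0.5 + 3P`), so the difference wave behaves like a textbook FRN while
  the separate signals violate axiom 2 — the dissociation the violation
  suite checks.
* All randomness derives from one session/study seed through a
  documented label-hash splitting scheme (`derive_seed()`), so any stage
  can be re-run in isolation bit-identically.
* Problem sizes used by the validation suites: the recovery study runs
  the full 17-subject, 540-trial, 275-channel configuration; null
  calibration uses 100 simulations of 12-subject 16 × 16 × 12 images,
  where the voxel-level F distribution is exact and scale plays no role;
  slope recovery is measured as cluster-averaged condition means over
  the primary interaction cluster and compared against a noiseless
  single-subject template extracted identically (single-voxel extraction
  confounds peak-selection noise with the estimate).

## Interfaces

Sessions round-trip through a portable directory container
(`write_session()` / `read_session()`): JSON metadata (version, sampling
rate, time axis, artifact record, append-only provenance), the epoch
array as little-endian IEEE-754 doubles, and CSV trial/layout tables;
round trips are bit-identical.  Configuration is a nested list mirrored
by YAML files (`read_config()`), with unknown keys rejected.  Reports
export to JSON plus TSV cluster tables (`export_report()`); identical
runs produce byte-identical exports.
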