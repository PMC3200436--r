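# axiomerf

Axiomatic tests for reward prediction-error signals in event-related M/EEG
sensor data.

## The problem

A reward prediction error (RPE) is the signed difference between an
outcome's value and its prior expectation: largest for the least likely
outcomes, zero for fully predicted ones.  Whether a given electrophysiological
signal *is* an RPE cannot be settled by showing a valence difference alone.
The axiomatic (Caplin–Dean) framework gives necessary conditions that any
candidate signal `S(valence, P)` must satisfy on a win/loss × outcome
probability design:

1. **Valence ordering** — wins and losses differ, at least for unlikely
   outcomes;
2. **Probability modulation of both valences** — the slopes of `S` against
   outcome probability are nonzero *within wins and within losses*,
   significantly different from each other, and of opposite sign
   (`S(win, P) ∝ +β(1−P)`, `S(loss, P) ∝ −β(1−P)`);
3. **Equivalence at P = 1** — fully predicted wins and losses produce the
   same signal.

`axiomerf` implements the complete sensor-space testing pipeline for this
battery, validated end to end by parameter recovery on synthetic data:

* **Session simulation** — a 540-trial gambling session (2 valence × 4
  probability design; exact-frequency outcome realization so realized
  frequencies match nominal probabilities), evoked components with dipolar
  topographies and condition-dependent gains, 1/f + white sensor noise,
  eye-blink and channel-jump artifacts.
* **Preprocessing** — zero-phase Butterworth filtering, resampling,
  baseline correction, amplitude-based trial rejection, signal-space
  projection (SSP) of blinks, mastoid re-referencing, and robust
  (outlier-downweighting) or plain condition averaging.
* **Scalp imaging** — azimuthal projection of the sensor array,
  triangulation-based linear interpolation onto a 64 × 64 grid of 3 mm
  pixels, Gaussian 8 mm × 8 mm × 8 ms FWHM smoothing, 100–600 ms temporal
  mask.
* **Mass-univariate ANCOVA** — win/loss regressors with mean-centred
  probability modulators (codes 4, 3, 2, 1), F contrasts for valence
  `[1 −1 0 0]`, probability `[0 0 1 1]` and the critical valence ×
  probability interaction `[0 0 1 −1]`; peak thresholding at p = 0.005
  with a 100-voxel cluster extent; an inclusive mask built by *inverting*
  a lenient (p < .05) map of win-vs-loss differences at P = 1.
* **Axiom battery and FRN** — window-averaged condition means at the
  interaction peak, repeated-measures ANOVA with a linear polynomial
  trend, per-probability paired tests, the three-axiom compliance grade,
  and the feedback-related-negativity (FRN) difference-wave analysis
  (minimum of loss − win within 0–600 ms).

## Worked example

```r
library(axiomerf)

# one synthetic subject: design, evoked components, noise, artifacts
session <- simulate_session(seed = 3)
session
#> Epoched data: 540 trials x 275 channels x 516 samples @ 600 Hz
#>   time: -160.0 .. 698.3 ms; 2 processing steps recorded

pp <- preprocess(session)        # resample, band-pass, baseline, reject, SSP
pp$n_rejected
#> [1] 5                           # the five injected channel jumps

imgs <- sensor_maps(pp$evoked)   # smoothed scalp-by-time image volumes
imgs[[1]]
#> Scalp image: 64 x 64 px (3 mm) x 101 frames; 2619 valid pixels
```

The full study (17 synthetic subjects, group ANCOVA, inclusive mask,
axiom battery) is one call:

```r
report <- run_pipeline(default_config(), seed = 1)
report
#> -- interaction contrast --
#> Clusters at p < 0.005 (F > 8.19), extent >= 100, df = (1, 116):
#>  cluster_id extent    peak_F   peak_Z  x_mm  y_mm t_ms
#>           1   8730 103.75124 8.511358  16.5 -13.5  310
#>  ...
#> interaction peak: x = 16.5 mm, y = -13.5 mm, t = 310 ms
#> Axiomatic compliance report
#>   axiom 1 (valence ordering):    pass
#>   axiom 2 (probability slopes):  pass  [win 6.76e-14, loss -1.96e-13, opposite signs: TRUE]
#>   axiom 3 (P=1 equivalence):     pass  [t = -0.15, p = 0.886]
```

The prediction-error component was injected at 320 ms; the masked
interaction analysis recovers a fronto-central cluster peaking at 310 ms
whose win and loss probability slopes are opposite in sign, and the
battery grades the signal compliant.  With the scalp-potential pattern
instead (both valences scaling *positively* with probability,
`simulate_eeg_study()`), the same battery flags an axiom-2 violation while
the difference-wave FRN still shows a significant probability effect —
the two qualitative regimes the method is designed to distinguish.

Reading the 2 × 4 design: `outcome_prob` is the probability of the
*realized* outcome, so a loss after a .25-win gamble is a P = .75 loss.
"45 gambles with 0 or 1 win probabilities" is read as 45 at each of P = 0
and P = 1 — the only reading that sums to 540 trials — which is also why
the two P = .75 cells collect 135 outcomes each even though the nominal
per-cell description is "approximately 45".

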