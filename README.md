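# trackrel

Markerless tumor tracking (MTT) localizes a lung tumor on kilovoltage
fluoroscopy by template matching, without implanted fiducials. Ribs and
spine can obscure the tumor on single-energy (SE) images; fast-kV
switching acquires alternating 60/120 kV pulses so each pair yields one
bone-suppressed dual-energy (DE) image by weighted logarithmic
subtraction, `DE = ln I_H − w_s · ln I_L`. Whichever stream is tracked,
the clinical question is frame-level: *can this tracked position be
trusted?*

`trackrel` is an analysis pipeline for that question, built and
validated entirely on synthetic fluoroscopy (the clinical images behind
the protocol it follows are not shareable). It provides, as tested R
functions:

- a digital thorax phantom and fast-kV acquisition simulator with
  known trajectories — cos⁴ breathing (`z(t) = A·cos⁴(πt/T)`),
  irregular patient-like breathing with jitter and drift, Beer–Lambert
  rendering, photon noise, inter-pulse misregistration;
- DE image generation: mutual-information rigid registration of each
  HE/LE pair plus weighted log subtraction (`w_s` = 0.69 phantom /
  0.42 patient by default, or calibrated from ROIs);
- template tracking: masked zero-normalized cross-correlation, peak
  localization, match score, peak-to-sidelobe ratio (PSR), missing
  frames;
- per-frame reference positions: the programmed waveform (phantom) or
  a constant-acceleration Kalman estimate (patient-like), reliability
  labels at the 2 mm criterion, tracking success rate (TSR), and
  poor/moderate/good stratification with midpoint-derived thresholds;
- the reliability model: a sample-weighted, regularized logistic
  regression on scaled match score, PSR and velocities with a domain
  indicator and interaction terms,

  `P(reliable) = σ(β₀ + β₁x₁ + β₂x₂ + β₃x₃ + β₄x₄ + β₅DI + β₆DI·x₁ + β₇DI·x₂ + β₈DI·x₃ + β₉DI·x₄)`,

  fitted per modality under leave-one-dataset-out cross-validation,
  with per-domain operating thresholds at 95% training specificity and
  an exact McNemar comparison of the SE and DE models.

## Worked example

```r
library(trackrel)
res <- run_study(study_config(master_seed = 1))
res$tables$comparison
```

```
    sens_se   sens_de   spec_se   spec_de    mcnemar_p
1 0.3630042 0.7112069 0.9432624 0.9536424 2.924799e-16
```

At operating thresholds targeting 95% specificity, the DE-stream model
classifies 71% of truly reliable frames as reliable versus 36% for the
SE-stream model, at matched specificity — the bone-suppressed stream is
the more trackable one whenever rib overlap is the dominant failure
mode, and the paired McNemar test on frame-level correctness puts the
difference far beyond chance. `res$tables` also holds the fitted
coefficients, the averaged per-domain thresholds, phantom metrics by
tumor size (5/10/15 mm), patient-like metrics by quality band, and the
held-out datasets' confusion metrics (one dataset per band).

The stepwise version of the same workflow lives in `analysis/01_*.R`
through `analysis/06_*.R` (simulate → dual-energy subtraction → track →
ground truth and TSR → model fitting → report), each writing its tables
under `results/`. For example, `analysis/03_track.R` prints:

```
SE stream: 60/60 frames tracked (dt = 0.133 s), median score 0.52, median PSR 1.9
DE stream: 60/60 frames tracked (dt = 0.133 s), median score 0.70, median PSR 7.5
```

— the DE stream's higher match scores and much sharper correlation
peaks are exactly the features the reliability model feeds on.

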