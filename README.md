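# emgregion

Where along the forearm should a compact electrode patch sit for
myoelectric gesture recognition? `emgregion` is an R package for studying
that placement question with high-density surface electromyography
(HD-sEMG): it implements a complete classification pipeline over a
256-channel four-array montage — feature extraction, spatial outlier
repair, dimensionality reduction, one-vs-all SVM classification under
three validation protocols, and nonparametric region comparison —
together with a synthetic HD-sEMG generator that emulates the full
acquisition design, so every stage is testable without any recordings.

It is aimed at researchers in myoelectric control and biomedical signal
processing who want a reproducible, leakage-audited reference pipeline for
electrode-placement and cross-day/cross-subject generalization studies.

## The method

Signals are organized as subject x day x gesture x trial x movement epochs
(1 s at 2048 Hz, 256 channels). Per movement, the pipeline:

1. band-pass filters 10–500 Hz (order-8 Butterworth, zero-phase) and
   notch-combs 50–400 Hz mains harmonics;
2. drops the 0.25 s reaction phase and slides a 500 ms window with 125 ms
   step (75% overlap), giving 3 windows per movement;
3. restricts to one 64-channel region (distal wrist, mid-forearm, or
   proximal elbow; each 4 axial rows x 16 circumferential positions) and
   extracts 8 features per channel — RMS, SSC, MYOP, skewness, WAMP,
   kurtosis, MNF, MDF (thresholds 0.05 V, 0.05 V, 4·10⁻⁵) — into a
   512-length vector;
4. screens each feature's 16 x 4 spatial map with a mean ± 2·sd criterion
   and replaces outlier cells by their nearest valid neighbours' mean;
5. z-scores and projects by PCA retaining the smallest D with ≥ 95%
   explained variance, D ≤ min(512, Nₛ − 1), fitted on training data only;
6. classifies with one-vs-all linear SVMs, C and γ grid-searched over
   {0.1, 1, 10} x {10⁻², 10⁻¹, 1} on a stratified 10% validation holdout.

Three protocols control leakage at the movement and subject level:
intra-subject (leave-one-movement-out per subject-day), inter-day (day 1
trains, day 2 tests) and inter-subject (leave-one-subject-out, day 1
only). Region differences are tested with the Friedman repeated-measures
test and pairwise Wilcoxon signed-rank tests with Bonferroni correction.

## Worked example

```r
library(emgregion)

cfg <- generator_config(n_subjects = 2, n_days = 2, n_gestures = 4,
                        n_trials = 1, snr_db = 10, seed = 7)
ds <- generate_dataset(cfg)           # 2 x 2 x 4 x 1 x 3 = 48 epochs
layout <- build_layout()

feats  <- feature_table(ds, select_region(layout, "distal_wrist"))
res    <- run_protocol(feats, "intra_subject", seed = 1)
res
#> <intra_subject protocol, region distal_wrist>
#>   mean accuracy: 1.0000 over 2 subjects (48 folds)

feats_p <- feature_table(ds, select_region(layout, "proximal_elbow"))
res_p   <- run_protocol(feats_p, "intra_subject", seed = 1)
res_p
#> <intra_subject protocol, region proximal_elbow>
#>   mean accuracy: 0.0625 over 2 subjects (48 folds)
```

The single-DoF gesture sources sit distally (near the wrist), so the
distal patch separates the four gestures perfectly at 10 dB SNR while the
proximal patch barely sees them at all and falls to chance level or
below. With
the `daily_use` gesture set — compound grasps sourced mid/proximally —
the ordering reverses. `run_protocol()` also returns per-subject scores,
per-fold logs and a pooled confusion matrix;
`compare_regions(cbind(...))` runs the Friedman + Wilcoxon region
statistics on matched per-subject accuracies.

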