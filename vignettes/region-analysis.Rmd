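---
title: "Forearm-region analysis of HD-sEMG gesture classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forearm-region analysis of HD-sEMG gesture classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

High-density surface electromyography (HD-sEMG) records muscle activity
with hundreds of closely spaced skin electrodes. For myoelectric control of
prostheses and other neuromuscular interfaces, a practical question is
*where along the forearm* a smaller electrode patch should sit: extrinsic
hand muscles concentrate distally (near the wrist), so a distal patch
should capture finger- and wrist-level gestures well, while compound grasp
gestures recruit larger, more proximal muscle bellies. `emgregion`
implements a complete pipeline for studying this placement question under
three validation regimes — within a session, across days, and across
subjects — together with a synthetic HD-sEMG generator so the whole chain
is testable without any recordings.

## The montage and its regions

The montage is four 8 x 8 arrays (256 channels, 10 mm pitch): two adjacent
arrays on the flexor side and two on the extensor side, forming a 16 x 8
grid per side along the proximal–distal axis. Row 1 is the most distal row.
Three 64-channel regions of 4 axial rows x 16 circumferential positions
are analysed: distal wrist (rows 1–4), mid-forearm (rows 7–10) and
proximal elbow (rows 13–16). The exact rows are configurable; the defaults
are maximally separated and symmetric, since physical montage drawings
typically leave the inter-region gaps ambiguous. Each region's 64 channels
carry a fixed raster order — per axial row, flexor columns 1–8 then
extensor columns 1–8 — so `matrix(v, 16, 4)` reproduces the spatial
feature map used for outlier screening.

## Signal model of the synthetic generator

Each gesture is a small set of activity sources on the 16 x 16 grid. A
source has a centre (axial row, circumferential position), a Gaussian
spatial footprint (`source_spread`, default 2 electrode pitches) and a
gain. Single-DoF gestures (11 labels) get distally biased row centres
(rows ≈ 1.5–5.5); daily-use compound gestures (10 labels) get mid/proximal
centres (rows ≈ 11–15). Source centres fan out around the circumference so
gestures are mutually distinguishable.

One movement epoch (1 s at 2048 Hz) is built as:

* per source, a Gaussian carrier band-limited to 20–450 Hz (4th-order
  Butterworth, the standard surrogate-EMG spectrum), normalised to unit
  RMS, modulated by a trapezoidal envelope (0.25 s reaction-phase rise,
  plateau, 0.1 s release) and projected through the spatial footprints;
* 50 Hz mains interference plus harmonics to 400 Hz with 1/k amplitude
  decay and random phases (`line_amp`, default 0.02 V);
* low-frequency (0.2–1 Hz) baseline drift with per-channel amplitude and
  sign (`drift_amp`, default 0.05 V);
* band-limited sensor noise at `amplitude_scale * 10^(-snr_db/20)` RMS.
  The sensor noise is shaped by the same 20–450 Hz filter because the
  acquisition chain band-passes at 10–500 Hz before sampling, so even
  channels far from every source stay band-concentrated.

Amplitudes are post-amplifier volts: `amplitude_scale` (default 0.1 V) is
the clean RMS of the best-coupled channel, which makes the conventional
0.05 V myopulse/Willison thresholds meaningful. The default `snr_db` of
10 dB represents a routine laboratory recording; +20 dB is used in the
package's reduced-scale verification study as a high-quality condition.

Inter-subject anatomical variability jitters source centres (sd 1 pitch)
and gains (log-sd 0.3) per subject; these defaults are chosen to make
cross-subject transfer visibly harder than within-subject classification,
as it is in practice. Day 2 displaces all source rows by
`interday_shift_rows` (default 0.5 pitch) and perturbs gains, emulating
array re-placement. Corrupted channels occur independently with
`p_bad_channel` (default 2%) and receive either a large constant offset or
12x amplified noise, emulating baseline jumps and poor contact.

Every random stream derives deterministically from one integer seed via
per-subject/day/movement sub-seeds, so regenerating a dataset with the
same configuration is bit-identical, independent of evaluation order.

What the generator does **not** emulate: motor-unit action potentials and
recruitment/firing statistics, volume-conductor anisotropy, electrode-skin
impedance, fatigue within or across trials, force variation, and
rest-period activity. Passing tests on this generator therefore validate
the *pipeline* — its bookkeeping, leakage control and sensitivity to the
spatial structure the generator encodes — not performance claims about
real recordings.

## Pipeline stages

**Filtering.** A 10–500 Hz Butterworth band-pass (design order 8) followed
by second-order IIR notches at 50, 100, …, 400 Hz (quality factor 30).
Both are applied zero-phase (forward–backward, odd-reflection padding with
steady-state initial conditions) so no group delay shifts the trim
boundary; the effective attenuation is the squared magnitude response.
"Order 8" names the band-pass transfer function itself.

**Segmentation.** The first 0.25 s reaction phase of each 1 s movement is
discarded; a 500 ms window slides in 125 ms steps (75% overlap), windows
overrunning the movement end are dropped. A 1 s movement yields exactly
three windows starting at 0.25, 0.375 and 0.5 s. Every window keeps full
provenance (subject, day, gesture, trial, movement, window index) — the
validation protocols depend on it.

**Features.** Eight per-channel features in fixed order: RMS, slope sign
changes (threshold 4e-5 V² on the slope product), myopulse percentage rate
(0.05 V), skewness, Willison amplitude (0.05 V), kurtosis, mean frequency
and median frequency. Moments are population-style and kurtosis is
non-excess (Gaussian → 3). MNF/MDF come from a Hann-tapered periodogram of
the full window restricted to the 10–500 Hz pass-band; Welch averaging is
deliberately not used on 1024-sample windows. Zero-variance or all-zero
windows return 0 for the moment and spectral features instead of NaN; such
windows only arise in synthetic edge cases. The 64 channels x 8 features
flatten channel-major into a 512-length vector. One vector is produced
*per window* (three per movement): the alternative reading — one vector
per movement — would discard the segmentation, and the within-session
protocol explicitly tests movements "with their three windows".

**Spatial outlier repair.** Each feature's 64 region values are reshaped
to the 16 x 4 map and screened with a mean ± 2 sd criterion computed over
that single map (sample sd; a constant map flags nothing). Flagged cells
are replaced by the mean of their valid 4-neighbours; cells with no valid
rook neighbour draw from the nearest valid cells by Euclidean grid
distance, all equidistant cells averaged. Euclidean shells were chosen
over Chebyshev rings because they are isotropic and agree with a
brute-force "nearest valid by grid distance" definition; the difference
only matters when an entire neighbourhood is flagged. One detection pass
is applied (no iteration), per feature map per window, and the map edge is
not wrapped circumferentially (the flexor and extensor arrays are
physically separate; a wrap option exists). Repair precedes normalization.

**Normalization and PCA.** Z-score statistics and the PCA projection are
fitted on the training partition of each fold only and applied unchanged
to its test partition. Although one could normalise all vectors jointly
before splitting, that leaks test statistics into training, contradicting
the protocols' no-test-data-in-tuning rule; fold-local fitting is the
default and a global-fit mode is intentionally not offered. The retained
dimensionality D is the smallest number of components reaching 95%
cumulative explained variance, capped by the number of feature dimensions
and by (training samples − 1); if the cap binds first, D equals the cap
and a warning is logged. Components carry a deterministic sign convention
(largest-magnitude loading positive) so refits are bit-identical.

**Classification.** One binary SVM per gesture (one-vs-all), linear kernel
by default, prediction by maximum decision value with ties broken by class
order. C and gamma are selected from {0.1, 1, 10} x {0.01, 0.1, 1} by
accuracy on a single stratified 10% holdout of the training set, ties
broken towards smaller C then smaller gamma. With a linear kernel the
gamma axis cannot change the decision function; the full 3 x 3 grid is
still evaluated for protocol fidelity, the no-op is asserted by a
regression test, and an RBF option makes gamma live. Binary learners are
libsvm fits (via e1071) behind the package's own one-vs-all surface.

## Validation protocols and aggregation

* **Intra-subject**: per subject-day, leave-one-movement-out; the held-out
  movement's three windows test, all other movements train. Per-subject
  score = mean over folds, then over the two days.
* **Inter-day**: per subject, all day-1 windows train and all day-2
  windows test — one score per subject.
* **Inter-subject**: leave-one-subject-out on day-1 data only; 19 subjects
  train, one tests — one score per subject.

Hyperparameters are re-searched in every fold by default; a `shared` mode
searches once per subject-day context and reuses the pair, which is
markedly faster and changes nothing when the grid is degenerate (linear
kernel). Every fold passes a leakage audit before use: train/test index
disjointness, no movement spanning both partitions, and subject
disjointness for the inter-subject protocol. Confusion matrices are pooled
over folds as counts and row-normalised only for reporting.

Region comparison uses the Friedman repeated-measures rank test across the
matched per-subject region scores (plain mean-rank chi-square; fully tied
data give statistic 0, p = 1), followed by pairwise Wilcoxon signed-rank
tests with Bonferroni correction. Zero differences are dropped before
ranking; the two-sided p is exact by sign enumeration up to 12 non-zero
differences (valid under tied magnitudes), exact via the signed-rank
distribution for untied samples up to 25, and a continuity-corrected
normal approximation beyond. p ≤ 0.05 is treated as significant.

## Problem sizes used in the shipped verification

The package's own tests and the acceptance script exercise a reduced-scale
cohort chosen as the smallest design that still contains every structural
element of the full study: 5 subjects x 2 days x 5 gestures x 2 trials x 3
movements (300 epochs per gesture set) at +20 dB SNR, with Monte-Carlo
properties replicated over at least 5 seeds at 1-subject scale. The full
20-subject, 11-gesture schedule is verified at the metadata level (counts
and fold structure), where synthesis is unnecessary.

## Known limitations

* The generator's class geometry is favourable (distinct source centres);
  absolute accuracies on it say little about real gesture confusability —
  only the relative orderings (region placement, protocol difficulty,
  SNR monotonicity) are meaningful.
* PCA/scaler fitting is per fold; studies that fit once per subject or
  per day will report slightly different numbers.
* The dataset writer uses a plain-text directory layout (CSV + JSON)
  rather than a binary container; it is meant for inspection and small
  exchanges, not bulk storage.
* Window-level spectral estimates use a single Hann-tapered periodogram;
  for much longer windows a Welch estimator would be preferable.

## A worked example

```{r}
library(emgregion)

cfg <- generator_config(n_subjects = 2, n_days = 2, n_gestures = 4,
                        n_trials = 1, snr_db = 10, seed = 7)
ds <- generate_dataset(cfg)
layout <- build_layout()
distal <- select_region(layout, "distal_wrist")

feats <- feature_table(ds, distal)
res <- run_protocol(feats, "intra_subject", seed = 1)
res$accuracy
res$per_subject

proximal <- feature_table(ds, select_region(layout, "proximal_elbow"))
res_p <- run_protocol(proximal, "intra_subject", seed = 1)
wilcoxon_bonferroni(res$per_subject, res_p$per_subject, m_comparisons = 1)
```
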