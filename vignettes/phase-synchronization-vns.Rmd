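---
title: "Phase-synchronization biomarkers of VNS response: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchronization biomarkers of VNS response: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic data generator does and does not
emulate, and where a genuinely open design choice was made.

## The analysis

The pipeline asks whether children with drug-resistant epilepsy who will
respond to vagus nerve stimulation (a 50% or greater drop in monthly
seizure frequency relative to the pre-implantation baseline) differ from
non-responders in the *phase synchronization* of their preoperative awake
scalp EEG, and whether that difference, combined with baseline clinical
features, predicts response.

1. **Preprocessing.** Recordings on the 19 standard 10–20 electrodes are
   resampled to 500 Hz, re-derived to a longitudinal bipolar montage (18
   anterior-posterior pairs), cut into non-overlapping 2-s epochs
   (half-open sample intervals), and screened by an amplitude/flatline
   artifact proxy. Epoching favours local stationarity, which the phase
   metrics assume.
2. **Connectivity.** Each epoch is band-pass filtered in the six clinical
   bands and Hilbert-transformed; PLV, PLI and wPLI are computed per
   unordered channel pair, averaged over epochs and then (unweighted)
   over pairs. The 18 global values (3 metrics x 6 bands) form a
   subject's synchronization feature vector.
3. **Group statistics.** Responder labels come from seizure diaries with
   inclusive reduction thresholds (>= 0.5 / >= 0.8 / = 1.0 for R50 / R80
   / R100; anything below 0.5, including worsening, is NR50). Each
   metric's five narrow bands are compared between R50 and NR50 with
   two-sided Mann-Whitney U tests and Benjamini-Hochberg FDR correction
   within the metric; clinical baseline variables get Mann-Whitney
   (continuous) or chi-square/Fisher (categorical) without correction, as
   is conventional for baseline tables.
4. **Prediction.** The 25-column clinical encoding (8 numeric fields,
   one-hot etiology/syndrome/MRI blocks, a *multi-hot* seizure-type block
   — seizure types co-occur — and two drug counts) is stacked with the 18
   synchronization features. A linear SVM is evaluated by stratified
   nested cross-validation: 10 outer folds estimate generalization, 5
   inner folds pick the cost parameter and the number of features per
   outer training set. Scaling, ranking and tuning are all refit inside
   each outer training fold; the held-out subjects touch nothing.

## Metric conventions

* Phase differences are wrapped to (-pi, pi].
* PLI uses `sign(0) = 0`, so a signal tested against itself gives exactly
  0; the sign at exactly pi is also taken as 0, because a constant-pi lag
  carries no lead/lag information either (the prose definition of the
  index excludes both 0 and pi from "1").
* wPLI is the population (non-debiased) form. When every imaginary
  cross-spectrum sample is exactly zero (identical signals, pure zero-lag
  mixing) the statistic is 0/0; the package returns 0 with a
  `degenerate` flag rather than erroring, so zero-lag fixtures flow
  through the pipeline.
* The first and last 10% of each epoch's samples are trimmed before the
  metrics are taken (Hilbert transforms of finite segments are least
  reliable at the edges). The fraction is configurable (`trim`).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `target_fs` | 500 | Hz | standard clinical digitization rate |
| `epoch_length_s` | 2 | s | stationarity vs. estimator variance |
| `amplitude_threshold_uv` | 200 | uV | movement/discharge artifact proxy |
| `flatline_eps` | 0.1 | uV | disconnected-channel proxy |
| `trim` | 0.1 | fraction | Hilbert edge suppression |
| `filter_order` | 4 | — | common EEG practice |
| `hilbert_scope` | `"epoch"` | — | see below |
| SVM `C_grid` | 0.01–100, log steps | — | spans under/over-regularized |
| `n_features_grid` | 5–43 | count | from sparse to all features |
| `min_select_frac` | 0.5 | fraction | coefficient-summary membership |

The artifact thresholds are a programmatic stand-in for visual review of
eye-movement artifacts and epileptiform discharges. They catch amplitude
excursions and dead channels; they make no claim of equivalence to expert
review.

## Numerical choices

* **Zero-phase filtering.** Phase is the payload, so the band-pass must
  not shift it. The package applies the *squared magnitude response* of a
  4th-order Butterworth — exactly the transfer function of a
  forward-backward (filtfilt) pass — as a real gain in the FFT domain, on
  segments reflectively padded by at least three time constants of the
  band's lower edge. This is phase-exact by construction and an order of
  magnitude faster than time-domain filtfilt; mid-epoch agreement with a
  time-domain filtfilt is ~1% (the residual is the bilinear-transform
  frequency warp, not phase error).
* **Resampling** is windowed-sinc polyphase (Kaiser beta 8, 10 zero
  crossings per side) with exact linear-phase delay compensation; a 10 Hz
  sinusoid resampled 1000 -> 500 Hz reproduces the closed form to ~1e-5.
  The `signal::resample` port was tried first and rejected after showing
  ~0.35 amplitude error on that fixture.
* **Per-epoch vs whole-series Hilbert** (`hilbert_scope`). Epoching is
  motivated by stationarity, yet a whole-series transform is the natural
  reading of "instantaneous phase of the recording". Both are
  implemented; per-epoch is the default. The choice matters for *null*
  data: on a 2-s epoch a narrowband pair has only ~2 x bandwidth
  effective samples, so per-epoch |mean sign| carries an O(0.2) positive
  bias that epoch-averaging cannot remove (the absolute value sits inside
  the average). Group comparisons are unaffected (the bias is common to
  both groups), but absolute statements like "PLI of independent mixed
  sources tends to 0 with duration" hold in the whole-series scope, and
  the volume-conduction property tests use it.
* **Mann-Whitney U** uses full enumeration of group assignments (exact,
  tie-aware through midranks) when the pooled sample has at most 12
  observations, and a tie-corrected, continuity-corrected normal
  approximation otherwise.
* **F-score ranking** defines constant features as score 0 (guarding
  0/0); ties break by column index, so rankings are deterministic.
* **Inner-CV ties** break toward fewer features, then smaller cost — a
  simplicity preference that keeps reports stable across seeds.

## The synthetic cohort generator

Each subject's EEG is a *common-driver* model: one narrowband oscillator
(centre of the coupling band, with mild phase diffusion so the spectral
line has width) drives all channels; channel `c` receives a fixed offset
`(c-1) * phase_lag` plus independent per-sample von Mises jitter with
concentration `kappa = tan(coupling_strength * pi/2)`, mapping coupling 0
to independent phases and 1 to rigid locking with analytic control of the
expected resultant. Independent Gaussian broadband noise is added, and an
optional symmetric zero-lag mixing matrix `(1-m) I + (m/n) J` emulates
volume conduction — the defining property being that it is real and
instantaneous, which inflates PLV but not PLI/wPLI.

Cohorts plant the group difference *only* in EEG coupling: responders
default to high-beta coupling 0.8 vs 0.4 for non-responders (phase lag
pi/4, noise SD 1, mixing 0.1), the canonical condition used throughout
the test suite. Clinical covariates are drawn from pooled distributions
matching a 70-patient pediatric DRE cohort (log-normal seizure
frequencies around ~690/month; BMI ~16.7; onset ~2.2 y; implantation age
derived as onset + duration for internal consistency; realistic category
frequencies for etiology, syndrome, MRI and the non-exclusive seizure
types) with *no* group effect, since no clinical variable separated
responders at baseline. Labels are drawn first (exactly
`round(n * responder_fraction)` responders) and diaries are made
consistent with them, so labeling-function tests have unambiguous ground
truth. All randomness flows from one seed through per-subject substreams
(a multiplicative-congruential splitting scheme), making any subject
reproducible in isolation.

The planted effect is *qualitative*: it reproduces the direction
(responders more synchronized in high beta, PLI/wPLI sensitive, other
bands null), not published group means; with the default settings it is
deliberately strong so calibration and power suites are stable at
desk-scale recording lengths. What the generator does **not** emulate: no
forward head model or 1/f background (volume conduction is a fixed
mixing matrix, noise is white), no ictal or epileptiform activity, no
real artifact morphology, no age dependence of the background rhythm.
Passing tests therefore demonstrate that the *machinery* — filtering,
phase estimation, metric identities, FDR calibration, leak-free CV — is
correct, not that the clinical effect sizes or accuracies of any real
cohort are reproduced.

## Design decisions on genuinely open points

* **Test choice for synchronization features.** Group comparison uses
  the FDR-corrected Mann-Whitney U test by default; an unpaired t-test
  mode (`method = "t_test"`) is available, as both appear in practice for
  such tables. The FDR family is the five narrow bands within one metric;
  the combined beta band is extracted as a classifier feature but not
  tested (it is a union of two tested bands).
* **Montage.** The longitudinal "double banana" (18 pairs over 19
  electrodes) is the default bipolar derivation and is configurable; no
  single montage is canonical.
* **"Principal components".** The per-feature outputs of the classifier
  are the mean +/- SD of the *standardized linear SVM weights* of
  features selected in at least half the outer folds, aggregated across
  folds. No PCA is performed anywhere; the term is avoided in the API.
* **External validation** refits the pipeline (scale -> select -> fit,
  settings from inner CV) on all discovery subjects, rather than
  ensembling fold models, and predicts the external matrix with
  discovery-only scaling.
* **Discovery/validation split** of a simulated pool (default 88 -> 70 +
  18) is a seeded random split; with ingested data the manifest carries an
  explicit role column.
* **Command-line surface.** The exported functions and `run_pipeline()`
  are the primary interface; `inst/cli/vnseeg` is a thin subcommand
  wrapper over them for shell use.

## Simulation sizes in the test suite

Monte-Carlo suites keep the cohort design of interest (n = 70, 37:33
responder split, 100 or 50 or 20 seeded replicates) but shrink what does
not affect the tested property: 2–3 channels, 8–10 s of EEG at 200 Hz for
cohort-level calibration and power; 60 s at 500 Hz (whole-series scope)
for the volume-conduction asymptotics; reduced but spanning hyperparameter
grids for the permutation-null CV calibration. These are the package's
choices of problem size for its own test design.

## Known limitations

* Global mean synchronization only — no graph-theoretic summaries, no
  directed metrics, no source space.
* The artifact screen is a threshold proxy; heavily contaminated real
  recordings need proper review or ICA upstream.
* The wPLI debiased-square estimator is not implemented.
* Very short recordings make per-epoch PLI/wPLI estimates biased upward
  (see `hilbert_scope` above); comparisons remain valid, absolute values
  should be read with the epoch length in mind.
* EDF support is minimal (continuous 16-bit EDF/EDF+); no annotations,
  no discontinuous records.
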