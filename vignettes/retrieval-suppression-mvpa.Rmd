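---
title: "Decoding retrieval suppression from EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding retrieval suppression from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tntmvpa)
```

## What the package computes

`tntmvpa` implements a complete multivariate analysis chain for
Think/No-Think (TNT) retrieval-suppression EEG experiments. In the TNT
paradigm, participants learn cue-target pairs and are then shown cues with
the instruction either to retrieve the associated memory (Think), to keep
it out of mind (No-Think), or to simply look at an unpaired cue
(Perceptual Baseline). A later cued-recall test scores memory on
Identification, Gist and Detail; recall of No-Think items below Baseline
is suppression-induced forgetting.

The analysis chain is:

1. **Decoding.** Epoched EEG (trials x 61 channels x time, -1000..3500 ms
   at 250 Hz) is reduced to 15 spatial PCA components. At every 20 ms
   timepoint (features averaged over +/-10 ms), same-class trials are
   randomly averaged into sub-ERPs (10 bins for condition decoding, 3 for
   item decoding), and a linear SVM is cross-validated with one sub-ERP
   per class held out per fold; train and test folds are z-scored with
   training statistics only. The whole procedure repeats over 10 random
   binnings. Condition decoding is binary (one-vs-one pairs of
   conditions, trials subsampled to the smallest condition, about 56);
   item decoding is one-vs-all over 12 (or 6) items with class counts
   matched to the least-frequent item.
2. **Empirical chance.** The identical classifier pipeline run on the
   pre-stimulus baseline (-500..0 ms), where no task information exists,
   estimates the chance level empirically rather than assuming
   1/k (`estimate_chance()`).
3. **Inference.** Nonparametric cluster-based permutation tests on the
   0..3000 ms window: pointwise t statistics are thresholded at cluster
   alpha 0.05, contiguous exceedances are summed into cluster masses, and
   the observed masses are ranked against a 1000-permutation null of
   maximal masses. Three null constructions mirror the three designs:
   re-assigning trial-level classification outcomes to random classes
   (vs chance, one-tailed), re-assigning condition labels to pooled
   trial records (paired condition contrasts, two-tailed, critical
   values at 2.5%/97.5% per tail), and shuffling group labels
   (independent-groups contrasts). Correlation timecourses are clustered
   after transforming Spearman's rho to t via
   `t = rho sqrt((n-2)/(1-rho^2))`.
4. **Time-frequency.** Morlet wavelets at 22 geometrically spaced
   frequencies from 2.8 to 30 Hz, cycles increasing linearly from 3 to 7,
   decibel baselining against mean -500..-200 ms power; band summaries
   for theta (4-8 Hz) and alpha (9-12 Hz). The same decoding engine runs
   per frequency bin for time-frequency decoding, with 2-D (rank-matched)
   cluster inference.
5. **Searchlight.** Channel neighborhoods from Delaunay triangulation of
   the 2-D projected montage; decoding restricted to each channel plus
   its neighbors maps the scalp origin of decodable information, with
   channel-cluster permutation contrasts.
6. **RSA.** Pairwise item decoding yields a neural representational
   dissimilarity matrix (RDM) per timepoint; rank correlations against
   averaged subjective dissimilarity ratings (1-9 scale, converted to
   dissimilarity as `10 - rating`) test whether neural geometry matches
   perceived cue or scene similarity.
7. **Behavioral statistics.** Repeated-measures ANOVA with
   Greenhouse-Geisser correction, planned paired contrasts with Cohen's
   dz (`dz = t/sqrt(n)`), median-split or exact 1-D 2-means subgrouping,
   Spearman brain-behavior correlations with Baseline normalization
   `(x - BL)/BL`, the Meng-Rosenthal-Rubin z test for dependent
   correlations, and exact noncentral-t power for paired designs
   (n = 36 at dz = 0.48 gives 80% power at alpha = .05).

## The synthetic experiment

Because real recordings are large and preprocessed upstream, the package
ships a generator (`sim_config()`, `simulate_participant()`,
`simulate_behavior()`, `simulate_subjective_ratings()`) that emulates the
study design with known ground truth. Per trial it sums:

* **1/f background noise** (`noise_sd`, default 2 uV; spectral slope 1),
  spatially correlated through a Gaussian volume-conduction kernel
  (sigma 0.5 rad of scalp angle) plus a 10% sensor-white component. The
  correlated kernel matters: it gives the steeply decaying spatial
  eigenspectrum of real EEG, which is what makes a 15-component spatial
  PCA an effective feature space.
* An **item-specific occipital cue pattern** (default 8 uV): a 6 Hz
  theta-band carrier plus an equal-weight mean deflection
  (`cos(2 pi f t + phi) + 1`), under a Hann envelope over 0-500 ms, in
  every condition - the perceptual trace of the cue picture. Real evoked
  responses carry both an oscillatory component and a mean deflection;
  a pure zero-mean carrier would cancel under the time-window averaging
  the searchlight and sub-ERP steps rely on.
* An **item-specific distributed scene pattern** (default 6 uV) with the
  same carrier-plus-deflection form at 10.5 Hz over 500-3000 ms, with
  gain 1 in Think,
  `1 - s` in No-Think and 0 in Perceptual Baseline, where `s` is the
  participant's suppression strength (drawn around
  `suppression_factor`, default 0.85; `s = 1` abolishes the trace) -
  memory reinstatement and its suppression.
* A **frontocentral theta burst with a negative mean deflection**
  (`cos - 0.6`) over 200-400 ms in No-Think only (default 4 uV) - the
  early inhibitory-control signature, visible both as a theta power
  increase and as an N450-like frontocentral negativity.
* **Ongoing posterior alpha** (default 2 uV, random phase per trial)
  over 500-3000 ms, its power reduced by `alpha_mod` (default 0.3) in
  No-Think - the sustained oscillatory condition effect.

Item patterns are drawn randomly within their scalp region (cue patterns
keep at least 70% of their energy over occipital channels), smoothed by
the same volume-conduction kernel as the noise (scalp fields are smooth;
spatially rough patterns would be unphysical and would vanish under
spatial PCA), and given per-item strengths drawn from U(0.6, 1.4).
The strengths are what give the item set a non-trivial geometry:
independent high-dimensional patterns are nearly equidistant, leaving an
RDM with almost no variance for RSA to recover. Evoked oscillations are
phase-locked with one common phase per participant, so item identity is
carried purely spatially and pairwise pattern distances are preserved at
every timepoint; because the instantaneous carrier still dips near zero
once per cycle, window-level RSA summaries should use
`average_rdm_series()` over a phase-diverse set of timepoints rather
than a single timepoint.

Behavioral scores couple to the EEG ground truth through the Detail
deficit `a + b (s_i - s_bar) + e`, with `b = 2` Detail points per unit
suppression strength, `sd(e) = 1`, and the intercept solved so the
population Baseline - No-Think effect size equals `forgetting_dz`
(default 0.34). Subjective ratings are noisy linear transforms of
pattern distances onto the 1 (extremely dissimilar) to 9 (extremely
similar) scale, with per-rater noise (sd 1) over `n_raters = 22` raters.

### What the generator does and does not emulate

It reproduces the trial structure (12 + 12 + 6 items x 10 repetitions),
epoch geometry, the qualitative effect map (early occipital item
information everywhere; late distributed item information only where
retrieval happens; an early frontocentral theta condition effect; late
alpha reduction under suppression), behavioral forgetting with the
published effect size, and rating geometry coupled to the neural
geometry. It does not emulate real head-model forward projection, eye or
muscle artifacts, non-stationary noise, latency jitter across trials, or
item-specific ERP latencies. Passing recovery tests on this generator
therefore demonstrates that the pipeline detects the modelled class of
effects at the modelled SNR - not that any particular real dataset will
yield them.

### SNR calibration

Single-trial SNR is not something the published literature pins down, so
the default amplitudes are a calibration, not ground truth: they were
chosen once so that a desk-scale study (a handful of participants,
reduced decoding grids) reproduces the qualitative result map - item
decoding a few accuracy points above chance with significant clusters in
the right windows, searchlight maps localizing correctly, and RSA
correlations recoverable. Relative to real EEG the pattern amplitudes
are generous; the alternative (realistic amplitudes, 40 participants,
full grids) costs orders of magnitude more compute for the same
qualitative checks.

## Numerical and design choices

* **Windows** are half-open `[start, end)` ms everywhere; 0 = cue onset.
  Edge-inclusion conventions are otherwise arbitrary and this one is
  fixed and documented.
* **PCA before the train/test split**, fitted per participant on all
  trials and timepoints pooled, mirroring the published order of
  operations; the mild leakage this could in principle introduce is
  bounded by the leakage probe (adding a huge constant to test folds on
  null data must not, and does not, lift accuracy above chance, since
  z-normalization uses training statistics only). A strict per-fold PCA
  was considered and not implemented: the fold unit is the sub-ERP bin,
  so a per-fold fit would re-run PCA inside every bin x iteration x
  timepoint combination for a bias the probe shows to be negligible.
* **SVM**: linear kernel, C = 1, via libsvm (e1071). One-vs-one voting
  for condition decoding, one-vs-all with maximal decision value for
  item decoding; ties resolve toward the lowest class index. The
  published analyses name SVM + ECOC without stating kernel or C; these
  defaults are flagged as this package's choices.
* **Morlet edges**: Gaussian support truncated at 3 sigma; samples whose
  wavelet overhangs the epoch are `NA`, never zero-padded. At 2.8 Hz
  this invalidates roughly the first and last half second, so dB
  baselining uses the valid subset of the -500..-200 ms window at the
  lowest frequencies.
* **dB baseline** is the mean over trials and window samples per channel
  x frequency, pooled over conditions - the stable convention; trialwise
  baselining is noisier and not what group-level dB maps usually mean.
* **Cluster-forming threshold** is the parametric critical t at cluster
  alpha 0.05 with the design's df; permutation p-values use the
  `(b+1)/(m+1)` convention so p is never 0; two-tailed schemes form
  positive and negative clusters separately with per-tail criticals at
  2.5%/97.5%. For 2-D (time x frequency) maps the k-th largest observed
  cluster is compared against the null distribution of k-th largest
  masses (rank matching).
* **Neighborhoods**: Delaunay triangulation (Bowyer-Watson) of the
  azimuthal-equidistant projection, union of the plain and two
  axis-compressed (x/2, y/2) triangulations, edges longer than 1.6x the
  median pruned. The compression union and pruning factor were
  calibrated once against the montage's published characterization of
  about 6.4 (+/- 1.5) neighbors per channel; on the packaged montage the
  graph realizes mean 6.393, sd 1.49.
* **Median split** ranks by score then participant order, first half
  low; `kmeans2` is the exact 1-D two-cluster solution (all split points
  scanned), so both subgroupings are deterministic.
* **Rating scale direction**: the rating task is named a dissimilarity
  rating but anchored 1 = extremely dissimilar, 9 = extremely similar;
  the package reads the anchors (similarity) and converts averaged
  ratings to dissimilarity as `10 - rating`, with
  `direction = "dissimilarity"` available for the opposite reading.
* **Pre-stimulus RSA values** are computed but flagged (`prestim`), so
  suspicious baseline-window correlations are visible rather than
  pooled.
* **Seeds**: every stochastic stage (binning, subsampling, permutations,
  simulation) derives its own stream from a master seed via
  `derive_seed()`, so results are reproducible and stages are
  independent.

## Problem sizes used in the shipped checks

The test-suite and demo runs are scaled-down studies chosen to exercise
every code path at desk scale: typically 2-6 simulated participants
(100 Hz, 6-8 items, 6 repetitions) for recovery checks, 20 simulated
participants at the full design for chance-level estimation in the
acceptance script, 200 replicate datasets with 200 permutations per
scheme for false-positive calibration, and decoding grids of 40-100 ms
steps with 2-4 binning iterations. The full published design (40
participants, 20 ms grid, 10 iterations, 1000 permutations) is what the
defaults encode; nothing in the implementation depends on the reduced
sizes.

## Known limitations

* Condition-level decoding of Think vs Perceptual Baseline in the
  generator rests entirely on item-specific scene patterns, which
  largely average out of sub-ERPs; a dedicated condition-general
  retrieval component is deliberately not part of the generative model,
  so simulated T-vs-PB condition decoding is weak even where item
  decoding is strong.
* Cross-validated accuracy on null data sits slightly below the nominal
  1/k with small trial counts (the familiar anti-correlation between a
  held-out bin and the training mean); the empirical chance estimator
  measures exactly this quantity, which is why it - and not nominal
  chance - is the right reference.
* The subjective-rating simulator ties ratings to one participant's
  pattern geometry; real rating samples are independent of any EEG
  participant and noisier.
* No continuous (raw) EEG support: the containers start at clean epochs
  by design.

## A minimal run

```{r, eval = FALSE}
cfg <- run_config(sim = sim_config(n_participants = 6), n_perm = 200,
                  decode_step = 100, decode_iterations = 3,
                  master_seed = 1)
run_pipeline(cfg, "demo-run")   # writes report.txt and manifest.json
```
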