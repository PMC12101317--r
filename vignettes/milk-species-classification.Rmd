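---
title: "Classifying the species of origin of milk from MALDI-TOF peak lists"
author: "maldiMilk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the species of origin of milk from MALDI-TOF peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldiMilk)
```

## The problem

Sheep and goat milk command higher prices than cow milk, which makes
substitution with bovine milk a recurring authentication problem for the
dairy industry. MALDI-TOF mass spectrometry of the casein fraction gives a
fast, cheap fingerprint of a milk sample: caseins are species-specific in
mass, so the peak pattern between 3,000 and 10,000 Da carries the
species-of-origin signal. maldiMilk implements the downstream half of such
an assay: it starts from the peak lists exported by the acquisition
software (it does not do peak picking, smoothing or baseline subtraction,
which happen in the vendor software before export) and ends at a
cross-validated three-class classifier — bovine, goat, sheep — plus an
estimate of the composition of two-species mixtures.

Every peak row carries eight quality-annotated features, in fixed order:
m/z (Da), acquisition time, intensity, signal-to-noise ratio (S/N),
resolution, peak area, relative intensity and FWHM. These eight numbers per
consensus peak are the classifier's whole input; a consensus *vector* (one
peak averaged across replicate runs) is the unit of classification, not a
whole spectrum.

## The pipeline

1. **Quality control** (`qcFilter`). A row survives only if intensity
   >= 1000 a.u., S/N >= 5 and resolution >= 400 — all inclusive — and no
   field is missing. The thresholds are `qcThresholds()` arguments; the
   defaults are the values we consider standard for linear-mode protein
   spectra of this kind.
2. **Cross-run consensus** (`consensusVectors`). Replicate runs of one
   sample are reconciled peak-by-peak: for every surviving row of every
   run, the single closest-mass row of each *other* run is located, rows
   within a tolerance join the match set, and the consensus vector is the
   element-wise mean of all eight features over the set. The output has
   exactly one vector per input row, so n rows across the runs give n
   vectors. Two decisions here were genuinely open and are worth stating:

   * *Matching tolerance.* Peak lists carry no natural pairing, so a mass
     tolerance is required. The default is 2.0 Da, which is 200 ppm — a
     routinely calibrated instrument's mass accuracy — at the top of the
     3,000–10,000 Da window. It is a `tol` argument everywhere.
   * *Matching rule.* We use per-row nearest-neighbour matching, one
     candidate per other run, non-exclusive (a row may serve as neighbour
     to several seeds), with distance ties broken toward the lower mass,
     and no deduplication of near-identical vectors. This is the only
     reading consistent with producing one vector per row; the alternative
     — exclusive one-to-one assignment — would change the output length.
     An exhaustive brute-force implementation of the same rule serves as
     the test oracle.
3. **Robust scaling** (`fitRobustScaler` / `applyRobustScaler`). Each
   feature is transformed as x' = (x − median) / IQR. Peak features are
   heavy-tailed and the informative peaks *are* outliers, so median/IQR
   scaling is preferred over z-scoring. The IQR uses linear-interpolation
   quantiles (R type 7) — IQR is convention-dependent, so the convention is
   fixed and tested. A feature with IQR exactly 0 keeps divisor 1 and is
   flagged. The scaler is always fitted on the training split only and then
   applied to both splits; fitting it before splitting would leak test
   information through the medians.
4. **Classification** (`fnnTrain` / `predictProba`). A feedforward network
   maps the scaled 8-vector through four hidden layers of 64 ReLU units to
   a 3-way softmax. Training minimises class-weighted categorical
   cross-entropy by mini-batch Adam: 25 epochs, batch size 32, step size
   1e-3, moment decays 0.9/0.999, epsilon 1e-7, Glorot-uniform
   initialisation, predicted probabilities clipped at 1e-7 inside the log.
   The class weights are the balanced scheme w_c = N/(3 n_c) computed on
   the training fold (`computeClassWeights`), applied as per-sample loss
   multipliers — not by resampling — so the under-represented bovine class
   is up-weighted by exactly the inverse of its frequency. No early
   stopping, dropout or weight decay is used. Everything, including the
   per-epoch shuffle, is reproducible from one seed.
5. **Evaluation** (`crossValidate`). Non-stratified uniform 10-fold
   cross-validation; each fold refits the scaler and class weights on its
   training split. Reported per fold and as mean ± sd: unweighted mean
   cross-entropy, categorical accuracy (confusion-matrix trace over total),
   micro one-vs-rest precision and recall, and macro one-vs-rest ROC-AUC.
   Hard test-fold predictions are aggregated into a single confusion matrix
   covering every vector exactly once. Two metric conventions deserve a
   note. First, precision/recall are computed at a 0.5 probability
   threshold pooled over the three one-vs-rest problems: with argmax
   decisions, micro precision, recall and accuracy collapse into one
   number, which cannot represent the distinct values a practitioner
   expects to report, so the thresholded variant is primary (an undefined
   ratio is reported as `NA`, never as 0). Second, test loss is unweighted:
   class weights shape training, not evaluation. ROC points are produced by
   a threshold sweep with tied scores grouped and trapezoidal integration;
   the Mann–Whitney U normalisation and pROC serve as independent oracles
   in the tests, not as the implementation.
6. **Mixtures** (`evaluateMixture`). A mixture sample's composition is
   estimated as the mean predicted probability vector over its consensus
   vectors. The per-sample error is the largest deviation of the nominal
   component classes from their nominal proportions (for a 50/50
   goat/sheep mixture, max over goat and sheep of |p̂ − 0.5|), and the
   average error is the mean over samples. A probability-vector estimate of
   composition need not sum to the nominal design exactly; occasionally a
   reported pair like 0.48/0.51 does not follow any simple deviation rule,
   which is why the rule is exposed as `mixtureError` and tested on its
   own.

## The synthetic-data generator

Instrument data cannot ship with a package, so `generateDataset` produces
peak-list datasets with the statistical structure the analysis assumes.
What it emulates, and the defaults:

* **Species fingerprints.** Each species has a fixed set of base masses in
  [3000, 10000] Da (`defaultSignatures`): 27, 27 and 26 masses for bovine,
  goat and sheep, matching the roughly 23–25 QC-surviving peaks per
  exported spectrum of the study design this generator mimics. A fraction
  `overlap` (default 0.4) of each fingerprint comes from a pool shared by
  all three species — homologous caseins — with shared base intensities,
  so overlap is a genuine separability dial: 0 gives disjoint
  fingerprints, 1 identical ones. `minSep` (default 15 Da) keeps distinct
  masses apart.
* **Replicates and jitter.** Three runs per sample (triplicate
  acquisition); observed m/z = centre × (1 + ε), ε ~ N(0, 200 ppm), the
  calibration accuracy of a routinely calibrated instrument.
* **Peak quality.** Intensity is log-normal about the per-mass base value
  (CV 0.35), S/N log-normal with median 20, resolution N(800, 150); rows
  destined to pass QC are truncated at the thresholds, and with probability
  `qcFailRate` (default 0.1) a row is instead degraded below one threshold
  chosen uniformly. FWHM = m/z / resolution, area follows a Gaussian peak
  shape (1.0645 × intensity × FWHM), relative intensity is normalised to
  the run maximum, and acquisition time grows as sqrt(m/z), as in a linear
  TOF.
* **Class imbalance.** Default samples per species are 6 : 14 : 22 —
  a 1/36 scale of the 648 : 1,554 : 2,392 per-species spectrum counts of
  the study whose conditions the defaults encode — so the emitted
  consensus-vector proportions approximate the 16,018 : 38,394 : 55,055
  class imbalance that motivates class weighting.
* **Mixtures.** `generateMixtureSample` includes each component species'
  base masses with Bernoulli(proportion) and scales their intensities by
  the proportion, so a (1, 0) mixture reproduces the pure generator.

What it does **not** emulate: isotope envelopes, matrix adducts, chemical
noise peaks, intensity drift between sessions, or any correlation between
a sample's biological covariates (breed, lactation stage, season) and its
spectrum. Passing tests on generated data therefore demonstrate that the
pipeline's machinery is correct and that the classifier can learn
mass-pattern structure — they do not certify field performance on real
spectra, which depends on biological variability the generator does not
model.

## Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation) for median and IQR; IQR 0 →
  divisor 1, flagged.
* Softmax is max-stabilised; cross-entropy clips probabilities at 1e-7.
* Argmax ties in hard predictions go to the lowest class index.
* Consensus distance ties go to the lower mass; runs are kept mz-sorted.
* Empty runs are allowed after QC (flagged, counted); a sample whose rows
  all fail QC contributes no vectors, and a dataset with zero surviving
  vectors is a hard pipeline error.
* A cross-validation fold whose training split misses a class is skipped
  with a warning rather than silently producing a two-class model.
* Training aborts with a diagnostic on a non-finite loss.

## Problem sizes used in the shipped checks

The package's own benchmarks run at desk scale, chosen once: the
well-separated end-to-end benchmark uses three 6-mass fingerprints with
150 Da spacing and ~5,000 consensus vectors under 10-fold cross-validation;
the separability-degradation check uses ~440-vector datasets over three
overlap/jitter levels and three seeds at 5 folds; class-weight checks use
the full printed class composition (109,467 labels), which costs nothing
because only label counts matter. File-format round-trips use CSV; xlsx is
supported as a read-only vendor-export input, with CSV as the pipeline's
native format.

## Known limitations

* The consensus rule assumes replicate runs of the *same* sample; it is not
  a cross-sample peak aligner.
* The classifier sees peaks independently; it never aggregates a whole
  spectrum's evidence except in mixture evaluation, where vector-level
  probabilities are averaged.
* Balanced class weights assume the training composition is representative;
  with stratification off (the default), fold-to-fold weight variation of a
  few tenths of a percent is expected and normal.
* Mixture composition estimates are probability means, not calibrated
  concentration estimates; mapping them to volume or protein fractions
  would require a calibration curve on real mixtures.
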