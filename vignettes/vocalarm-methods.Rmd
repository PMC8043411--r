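---
title: "Methods: roughness, categorization, and perceptual decisions on scream calls"
author: "vocalarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: roughness, categorization, and perceptual decisions on scream calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalarm)
```

## What the package computes

Human screams come in several affective flavors — pleasure, sadness, joy,
pain, fear, anger, plus an intense neutral vocalization of the vowel /a/ —
and only a subset of them ("alarm screams") signals danger. `vocalarm`
implements the four analysis families used to characterize this taxonomy:

1. **Roughness via the modulation power spectrum (MPS).** Each clip's
   log-amplitude, log-frequency spectrogram is Fourier-transformed in 2D,
   yielding power over temporal modulation rate (Hz) and spectral modulation
   density (cycles/octave). Perceptual roughness corresponds to temporal
   modulation energy in two bands, roughly 50–70 Hz and 140–180 Hz. Group
   contrasts over the MPS plane are tested with a label-shuffling
   permutation null, and per-scream band power predicts alarm ratings in an
   ordinary least-squares regression.
2. **Acoustic classification.** An 88-dimensional acoustic feature table is
   z-normalized and classified with a 1-vs-1 support-vector machine
   (third-order polynomial kernel) under stratified 5-fold cross-validation
   in which every sound is tested exactly once, plus cross-corpus
   classification (train on one vocalization corpus, test on another).
3. **Exhaustive alarm categorization.** The six scream types are split into
   an "alarm" and a "non-alarm" category in every admissible way (2–4 types
   per side, neutral always its own third level): 25 unordered partitions.
   Each is scored by a repeated-measures one-way ANOVA on per-rater level
   means of alarm ratings; the maximum-F split wins.
4. **Behavioral decision metrics.** From 7-alternative forced-choice (7AFC)
   logs: confusion matrices, misclassification-choice "false-alarm" rates,
   and one-vs-rest sensitivity `d' = Z(hit) − Z(false alarm)`. From 2AFC
   logs over all 21 type pairs: per-pair paired t tests on RT and accuracy
   with Benjamini–Hochberg correction, and a 4-level combination-category
   ANOVA (neutral-vs-scream, within non-alarm, alarm-vs-non-alarm, within
   alarm).

A synthetic-data module generates audio, feature tables, rating tables and
trial logs with planted structure, so the full pipeline is testable without
any external recordings.

## The synthetic generators and what they emulate

The generators reproduce the *statistical shape* the analyses assume, at the
reference design sizes: 12 speakers × 7 types × 5 instances = 420 clips
(with a 16 × 7 × 4 = 448-clip affect-burst counterpart and a 6 × 7 × 2 = 84
clip behavioral selection), 23 raters, 33/29/35-participant behavioral
samples, 3,000-ms response windows, a 6.53% 7AFC miss rate and 1.55% for
2AFC.

**Audio.** A scream-like clip is a harmonic carrier (f0 plus six harmonics at
1/k amplitude) multiplied by `1 + am_depth · b(t)`, where `b(t)` is
band-limited noise confined to the planted modulation band(s), plus 5%
broadband noise. Alarm types carry both roughness bands at depth 0.8;
pleasure and sadness carry the low band at 0.5; joy weakly (0.2); neutral is
unmodulated. These depths are free parameters (no acoustic ground truth
exists for them); they are chosen so that the bands the MPS analysis must
detect are present where the taxonomy says they should be. The clips are
not perceptually validated screams, and nothing here models vocal-tract
acoustics, formants, or f0 contours — conclusions from passing tests concern
the *analysis code*, not human vocalization.

**Feature tables.** Class means sit on a regular simplex (centered unit
vectors) scaled by `separation` and randomly rotated into the 88-dimensional
space; within-class covariance is the identity. Pairwise class-mean distance
is therefore `sqrt(2) · separation` within-class SDs. Real acoustic features
are correlated and heavy-tailed; this generator only fixes the property the
classifier tests rely on (controllable class overlap, exact chance at
separation 0).

**Rating tables.** Each rater rates each scream as its type's latent mean
plus Gaussian noise (SD 0.1), clipped to the [0, 1] rating scale. Defaults:
alarm 0.8, non-alarm 0.4, neutral 0.6.

**Trial logs.** 7AFC responses are drawn from a row-stochastic confusion
matrix; trials are missed with a fixed probability; RTs are log-normal per
type, truncated at the response window by inverse-CDF sampling (the data
motivating the package report only mean RTs, so any right-skewed family
serves; log-normal is conventional and easy to parameterize). 2AFC logs
contain one 72-trial block per type pair.

Every generator is a pure function of its arguments including the seed.

## Why the neutral rating mean sits between the categories

The alarm-categorization search ranks all 25 splits by their
repeated-measures F. Its error term has only `2·(n_raters − 1)` degrees of
freedom, so the F ratio between the planted split and its nearest rivals
(those that move a single type across the category boundary) fluctuates by
roughly ±10–20% *regardless of the rating noise SD* — scaling the noise down
scales both sums of squares equally. Recovery of the planted split is
therefore governed by the *shape* of the three latent level means, not by
the noise level. If the non-alarm mean sits exactly halfway between neutral
and alarm, the nearest rival split has *identical* population between-level
variance and recovery is a coin flip.

Because the neutral vocalization forms its own ANOVA level in every
candidate split, its latent mean carries no information about the alarm
partition. Placing it midway between the category means (0.6 between 0.4
and 0.8) maximizes the margin by which the planted partition wins: the best
rival achieves only 58% of the planted split's between-level variance, and
recovery at 23 raters / SD 0.1 is essentially certain. Empirical ratings
place neutral *below* non-alarm screams; the generator deliberately departs
from that one feature of real data in exchange for an identifiable planted
structure, and `make_rating_table()` exposes all three means for users who
prefer realism over margin.

## Spectrogram and MPS parameters

* **Gaussian window SD 1.5 ms** (support ±4 SD). A Gaussian window of SD σ
  attenuates envelope modulations at rate f by `exp(−2π²σ²f²)`; 1.5 ms
  passes 85% at 60 Hz and 32% at 160 Hz, so both roughness bands survive
  into the spectrogram. (An 8-ms window — a natural choice for speech —
  attenuates 60 Hz by ~39 dB and annihilates 160 Hz entirely; it cannot be
  used here.) The price is coarse frequency resolution (σ_f ≈ 106 Hz),
  acceptable on a log axis spanning 100 Hz–8 kHz.
* **Hop 2 ms**, placing the temporal-modulation Nyquist at 250 Hz, above
  the 200-Hz low-pass bound of the analysis.
* **128 log-spaced bins, 100 Hz to min(8 kHz, Nyquist)**; log magnitude
  floored 80 dB below the maximum.
* The log-spectrogram is **mean-removed** before the 2D transform so the DC
  bin does not dominate; group differences are unaffected.
* Power is normalized as `|FFT|²/(Nt·Nf)`, making the total over the full
  unfolded plane equal the squared norm of the mean-removed spectrogram
  (Parseval; asserted in the tests at 1e−6 relative).
* The grid keeps the full ±ωt axis and the non-negative ωs half; band
  statistics fold to |ωt|. Truncation bounds: 200 Hz and 12 cycles/octave.
* Permutation p-values use the add-one estimator
  `(1 + #{|diff| ≥ |obs|})/(n_perm + 1)` — never exactly zero — with the
  per-bin difference of group means as the statistic. The reference
  permutation count is 2,000; the calibration tests use 500, where the
  discreteness step (1/501) is far below the KS tolerance at the tested
  sample sizes.

## Classifier settings

Beyond "third-order polynomial, 1-vs-1", SVM internals are fixed for
reproducibility: cost C = 1, `coef0 = 1`, libsvm's default gamma (1/88),
features pre-scaled by the z-normalization step. `coef0 = 1` (the
inhomogeneous kernel `(γ·u·v + 1)³`, the form MATLAB's toolboxes use) is
deliberate: the homogeneous cubic spans only degree-3 monomials, cannot
express the linear Bayes boundary of Gaussian class clusters, and measurably
caps accuracy on separable synthetic data. Voting ties are broken toward
the earliest class in the canonical taxonomy order. Fold assignment is
stratified within class from a recorded seed, guaranteeing each sound is
tested exactly once.

Numeric equality with any particular toolbox's accuracy on real audio is
not a goal; the contracts tested are chance-level behavior under label
shuffling (±1 point of 1/7 over 100 shuffles), near-perfect accuracy at
high separation, and bookkeeping identities of the confusion matrix.

## Statistical core

* **rm-ANOVA**: the standard within-subject one-way decomposition. For k ≥ 3
  levels Mauchly's sphericity test runs on the covariance of k−1 orthonormal
  contrasts (chi-square approximation including the second-order expansion
  term); when it rejects at p < 0.05, Greenhouse–Geisser ε (the eigenvalue
  form, equal to the classical Box formula) rescales both degrees of
  freedom. ε is clamped to [1/(k−1), 1]. Effect size is partial η²
  (`SS_effect/(SS_effect + SS_error)`); the flavor is stated here because
  reports often leave it ambiguous.
* **d′ correction**: extreme hit/false-alarm rates are moved off 0/1 by the
  1/(2N) rule before the inverse-normal transform; N is the rate's own
  trial denominator. The false-alarm rate of the K-alternative task is
  one-vs-rest with trial-weighted pooling over non-target rows.
* **FDR**: Benjamini–Hochberg step-up via `p.adjust`, validated exactly
  against an independent transcription of the step-up definition. The 21
  RT tests and 21 accuracy tests form separate families.
* **Degenerate inputs**: a paired t on zero-variance differences, OLS on a
  rank-deficient design, correlation of a constant vector, and
  normalization of silence all raise errors rather than returning NaN;
  constant feature columns z-normalize to zero with a warning.

## Loudness normalization

Absolute SPL is not recoverable from digital audio, so "70 dB" maps to a
documented digital reference (RMS 0.05), and other levels scale by
`10^((L−70)/20)`. All analyses depend only on RMS equality across clips.
Fades are linear; normalization that would clip instead rescales to peak 1
with a warning, avoiding silent distortion of MPS content. The
loudness-delta analysis (one `20·log10` RMS ratio per clip against its mean
alarm rating) uses the Pearson machinery of the statistical core.

## Pipeline scale

`run_pipeline()` defaults are sized for a demonstration on one CPU: a
4-speaker × 7 × 2 corpus (56 clips, 0.8 s at 16 kHz), 96 frequency bins,
200 permutations per MPS contrast, the full 420 × 88 feature table for
classification, the full 23-rater × 420-scream rating table, and reduced
behavioral samples (12 participants). A full run takes a few seconds and is
byte-reproducible: rerunning with the same config yields identical MD5
checksums for every output file, which the manifest records. The test suite
and the acceptance script use these same scales, with the statistical
calibration suites (permutation null, chance-level classification) sized so
their binomial/KS tolerances are meaningful.

## Known limitations

* Synthetic audio is a detection target, not a perceptual stimulus; no
  claim about human screams follows from the generator itself.
* The MPS windowing trades frequency resolution for modulation bandwidth;
  analyses of spectral modulation above ~10 cycles/octave would need more
  frequency bins than the default.
* The permutation map is per-bin; no cluster-level correction over the MPS
  plane is implemented.
* The exhaustive categorization search is specific to the 6-type taxonomy
  (25 partitions); other taxonomies would need their own enumeration rule.
* `rm_anova` handles the one-way within-subject design only — no missing
  cells, no between-subject factors.
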