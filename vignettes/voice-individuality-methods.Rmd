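---
title: "Methods: age-robust voice individuality on synthetic two-period corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-robust voice individuality on synthetic two-period corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Voice individuality — the spectral signature that lets a listener or a
verification system recognize a particular speaker — is shaped by the
geometry of the vocal organs. Through adolescence those organs grow: the
fundamental frequency (F0) drops sharply in males, vocal-tract resonances
move, and a verifier trained on a teenager's voice may not recognize the
same person as an adult. The scientific question is whether some part of
the spectrum carries individuality that *survives* this change. Prior
work implicates the 1–2 kHz region and the 4–6 kHz region (the latter
linked to the shape of the piriform fossa, a vocal-tract cavity that
matures early).

`voiceinv` implements the full analysis pipeline for this question:

1. a **seeded source-filter generator** for two-period (unstable = immature,
   stable = mature) voice corpora with controllable, known ground truth;
2. **LFCC feature extraction** (linear-frequency cepstral coefficients,
   60 uniform bands over 0–8 kHz);
3. a **feedforward neural-network verifier** (`voice_verifier()`, the
   package's model object) scored by equal-error-rate (EER) accuracy over a
   swept decision threshold;
4. per-band **Fisher F-ratio** discriminability profiles per period;
5. a **band-median centroid resampling** that quantifies which frequency
   regions are robust to the period change.

Because no public longitudinal corpus spans adolescence for the same
speakers, the synthetic generator is a first-class, tested component: it
lets every downstream stage be checked against designed ground truth.

## The synthetic two-period corpus

Each synthetic speaker is a source-filter voice. The source is an impulse
train at the speaker's period-specific F0 with continuous intra-clip pitch
movement (a log-F0 random walk of about 0.6% per 10 ms plus a light 5 Hz
vibrato) and additive broadband aspiration noise (standard deviation 0.05
relative to unit impulses) shaped by the same vocal-tract envelope. The
filter multiplies, on the FFT grid, a −6 dB/octave glottal tilt (knee
800 Hz) with unity-peak Lorentzian resonances:

* **canonical vowel formants** (F1–F3 per Japanese vowel /a i u e o/, gains
  18/12/8 dB), shared by all speakers and identical in both periods;
* **invariant peaks**: one per speaker inside 1–2 kHz and one inside
  4–6 kHz (+12 dB, 150 Hz bandwidth), identical across periods, spaced at
  least 50 Hz apart across speakers — the designed carriers of age-robust
  individuality;
* **age-drift resonances** (+6 dB): one per period in each of three pools
  (0.3–0.75, 2.3–3.7, 6.3–7.5 kHz) chosen strictly outside the invariant
  regions, with the two periods' centers forced at least 35% of the pool
  width apart so vocal-tract growth always moves every such resonance. Their
  profile is a squared Lorentzian, which decays fast enough that the drift
  stays local to its own pool.

F0 defaults follow the adolescent-change literature qualitatively: males
180 Hz (unstable) → 120 Hz (stable), females 250 → 220 Hz, plus a
per-speaker offset of ±15 Hz; the male drop is much larger, as it is in
real voices. Per-clip F0 jitter is 5% in the unstable period and 3% in the
stable period (pitch control matures with age). Clips are
loudness-equalized to a fixed RMS of 0.1 (with a clipping guard), as
corpus recordings would be; without this, the per-clip gain would ride on
the F0-dependent alignment of harmonics with F1 and leak period
differences into every band.

The default corpus has 6 speakers (3 male-like, 3 female-like; the first of
each sex is a verification target), with **twice as many clips in the
unstable period** (6 phrase clips and 6 clips per vowel, versus 3 and 3),
mirroring the imbalance of longitudinal corpora in which mature-period
material is scarcer. Phrase clips chain five 0.2 s vowel-like segments with
10 ms cross-fades and occasional unvoiced noise bursts. Every clip is a
pure function of its seed; WAV output is 16-bit mono PCM at 16 kHz.

**What the generator does not emulate:** real phonetic content and
coarticulation, speaker-idiosyncratic formants (identity is deliberately
concentrated in the designed peaks and F0 so ground truth stays
interpretable), room acoustics and channel effects, and within-speaker
variation beyond pitch jitter and aspiration noise. Passing the
recovery tests therefore shows the *pipeline* extracts designed structure
correctly — it does not certify performance on real recordings.

## Feature extraction

Voice samples are 50 ms frames (800 samples) taken every 10 ms (40 ms
overlap) from the start of each clip, with trailing partial frames
discarded. Frames whose RMS falls below 10⁻³ of the clip peak are
eliminated as silence — a scale-free rule that removes digital silence
without touching quiet speech.

The LFCC of a frame is computed as: peak amplitude normalization to
[−1, 1] (per frame), Hamming window, FFT zero-padded to 1024 points,
squared magnitude, a 60-filter triangular bank with uniform linear
spacing over 0–8 kHz and 50% overlap between neighbours (their responses
sum to a constant over the interior), natural log of band energies floored
at 10⁻¹⁰, and an orthonormal type-II DCT. All 60 coefficients are kept.
The log step is the conventional cepstral definition; it can be disabled
(`log_energies = FALSE`) for the variant without it. The same front end
*without* log and DCT supplies the linear-domain band powers consumed by
the F-ratio.

The DCT is computed by the FFT even/odd reordering algorithm and is tested
against the explicit cosine-sum definition; the band edges are half-open
`[low, high)` intervals of width 8000/60 Hz.

## The verifier

`voice_verifier()` fits a feedforward network — input 60, hidden blocks of
affine → batch normalization → ReLU with widths 128/64/32, softmax output
over (target, non-target) — by mini-batch backpropagation with
cross-entropy loss and Adam (step 10⁻³, β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸,
the method's canonical defaults). Defaults are 300 epochs and mini-batches
of 32; weights use He-style scaled Gaussian initialization; there is no
early stopping or validation split. The seed controls initialization and
batch shuffling, so a fit is a pure function of its arguments. Batch
normalization uses batch statistics during training and frozen running
statistics (momentum 0.9) at inference, so prediction is side-effect-free.
Trailing mini-batches with fewer than two rows are skipped, since a batch
variance is undefined there. Analytic gradients are verified against
central finite differences in the test suite.

`train_ensemble()` fits five models (default) with seeds derived from one
master seed; the final verification accuracy is the mean of the per-model
EER accuracies.

For desk-scale runs the experiment driver caps the training set at 150
frames per speaker (a seeded subsample); with six speakers this gives
900-row training sets, which the default network fits in well under a
minute per model. The cap is a configuration entry
(`verifier$max_train_frames_per_speaker`).

## Threshold sweep, EER and accuracy

A sample is accepted as the target when its softmax target probability
*strictly exceeds* the threshold. FAR = FP/(FP+TN) and FRR = FN/(FN+TP)
are swept over thresholds 0.00, 0.01, …, 1.00; the EER is (FAR+FRR)/2 at
the threshold minimizing |FAR − FRR|, with ties broken toward the smallest
threshold (a deterministic rule; the sweep direction makes lower
thresholds the acceptance-friendly side). Verification accuracy is 1 − EER.
EER is computed per model and then averaged, not on pooled scores.

The 0.01 grid resolves every achievable FAR/FRR level when each class
contributes at least 100 samples (rates move in steps of one over the
class count); in that regime the grid EER agrees with an exhaustive sweep
of all distinct scores to within 0.01, which the tests verify. With very
small score sets the grid can miss narrow threshold intervals, so
evaluation on fewer than ~100 samples per class should be read with that
quantization in mind.

## Fisher F-ratio profiles

For period *s* and band *k*, with per-speaker mean band powers μ
and cohort mean μ̄ (speakers weighted equally, regardless of their sample
counts), the profile of speaker *i* is

F-ratio(i, s, k) = mean over speakers of (μ − μ̄)² divided by the
intra-speaker variance of speaker *i*'s samples in that band.

The numerator is shared by all speakers in a period; only the denominator
is speaker-specific — the profile is implemented exactly as this
definition reads. Band powers enter in the linear power domain. Each
(speaker, period) profile is min-max normalized across its 60 bands so
curves are comparable across periods. A zero intra-speaker variance yields
an `Inf` sentinel (flagged by a warning, mapped to 1 by the normalization)
rather than aborting a run. `band_region_report()` flags a region as
period-robust for a speaker when the mean normalized F-ratio inside the
region exceeds the mean outside in *both* periods.

One consequence of the shared numerator deserves note: a speaker's own
peak band has a *large* absolute intra-speaker variance (variance scales
with the squared magnitude), so each profile tends to rank the *other*
speakers' designed bands highest. Recovery is therefore assessed at region
level — the designed 1–2 kHz and 4–6 kHz regions should appear among a
profile's top-10 bands in both periods — and per vowel, since the
1–2 kHz signal is vowel-specific (it competes with F0 harmonics when
vowels are pooled).

## Band-median centroid robustness

Each vowel clip is turned into a magnitude spectrogram with the same
framing (50 ms Hamming, 40 ms overlap, 1024-point FFT, no silence filter
or per-frame normalization), and the median over all (frame, bin) cells is
taken per band. For one person, period and replicate, 50 random
(band, clip) draws from region A and 50 from region B are averaged into a
2-D centroid; the Euclidean distance between the two periods' centroids is
one distance sample, and 3000 replicates (6000 centroids) are drawn per
person and condition. Under the *invariant* condition the regions are the
bands inside 1–2 kHz and 4–6 kHz; under the *other* condition each
replicate draws two disjoint random band subsets outside both regions,
size-matched to the invariant ones.

Within a replicate the random band choices are **shared by the two
periods** while clips are drawn independently: the comparison is paired,
identical clips in both periods give a distance of exactly zero, and the
(large) between-band heterogeneity cancels instead of inflating both
conditions' distances. Median pairs are drawn across clips (not within a
single spectrogram), and the default distance analysis pools all five
vowels' clips per person. `distance_summary()` reports boxplot statistics
per person and condition and a one-sided Wilcoxon rank-sum test per person
of whether invariant-region distances are stochastically smaller.

## The experiment driver

`run_experiment()` executes the full design from one validated
configuration (`default_config()`, a plain list, or a YAML file): both
train/test period directions for each target and each utterance kind
(phrase plus the five vowels; 24 accuracy cells), F-ratio profiles and
region reports for phrase and vowel samples, and the centroid-distance
comparison. All randomness derives from the single master seed; the
report embeds a content hash of the configuration (output location
excluded). `validate_config()` reports every violation at once.

## Numerical choices and degenerate inputs

* Sub-seeds are derived from the master seed by string-tag mixing modulo
  2³¹ − 1, so every component is independently reproducible.
* All-zero frames are rejected by the feature pipeline (they should have
  been removed by the silence filter); all-zero clips yield zero band
  medians and empty sample sets rather than errors.
* Min-max normalization refuses vectors with fewer than two distinct
  finite values.
* FAR/FRR with empty denominators raise errors rather than returning NaN.
* The band containing 8 kHz exactly is the top band (intervals are
  half-open below it).

## Known limitations

* The generator's voices are far simpler than real speech; effect sizes
  (peak gain +12 dB, drift pools, noise floor −40 dB) were chosen once as
  plausible magnitudes that make the designed structure statistically
  recoverable at small cohort size, not calibrated to any real corpus.
* The verifier is a small dense network; no speaker embeddings, data
  augmentation or score calibration are provided.
* The F-ratio analysis reports no significance tests (none are defined for
  it here); the robustness analysis's rank-sum test is the only inferential
  statistic in the pipeline.
* With heavily quantized scores or tiny test sets the 0.01 threshold grid
  limits EER resolution, as described above.
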