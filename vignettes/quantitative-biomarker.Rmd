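---
title: "A decibel-scale EEG biomarker for animal-assisted therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decibel-scale EEG biomarker for animal-assisted therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datbio)
```

## The measurement problem

Assessing whether an animal-assisted therapy session changes a child's brain
state is usually done by subjective clinical scales. This package implements
an objective alternative built on single-channel frontopolar (fp1) EEG
recorded around a therapy session: about a minute at rest before the session,
the five-minute session itself, and a minute at rest afterwards, at
512 samples/s with a 0–255 "poor signal" quality flag (values at or below 51
mark a stabilized sensor; earlier samples are dropped by default).

Two descriptive analyses and one learned similarity measure are combined:

1. **Spectral description.** Welch's averaged-periodogram PSD, integrated
   over the canonical rhythm bands δ (0.5–4 Hz), θ (4–8), α (8–12),
   β (12–30), γ (30–60). Relative band powers are each band's share of the
   0.5–60 Hz broadband power, so they always sum to one. Because scalp EEG
   carries no neural content above 60 Hz, the Nyquist criterion
   (`fs >= 2 fmax`) would be satisfied by 120 samples/s; the 512 sps of the
   sensor is comfortable oversampling, which the pipeline exploits by
   decimating encoder inputs (below).

2. **Self-affine description.** Each phase's event-related average is turned
   into a cumulative profile, and the root-mean-square fluctuation of the
   linearly detrended profile is computed over log-spaced window sizes
   (a detrended-fluctuation-style analysis). The log-log curve is compared
   with its own least-squares reference line; a *crossover* — a sign change
   of the residual — marks a change of scaling regime. Per-phase crossovers
   `C_B`, `C_D`, `C_A` are summarized by
   `S_BA = |C_A − C_B|` (how completely the resting regime returns) and
   `S_DR = (|C_A − C_D| + |C_D − C_B|) / 2` (how far the session departs
   from rest). `S_BA` uses the absolute distance even though it is sometimes
   written without bars: the quantity is defined as a distance and all
   worked examples are non-negative. Crossover indices are reported 0-based
   on the curve's scale grid.

3. **Metric learning.** A shared-weight 1-D convolutional encoder is trained
   so that epochs from the same state (rest vs during-therapy) embed close
   together and epochs from different states embed far apart, using either
   the pairwise contrastive loss or the triplet loss
   `Σ [D_ap² − D_an² + α]₊`. At query time the trained encoder embeds a
   resting recording and a during-therapy recording, and their Euclidean
   distance `D` is mapped to a similarity `S = 1 − D/2 ∈ (0, 1]`
   (embeddings are unit-normalized, so `D ∈ [0, 2]`), from which the
   biomarker is

   `QB = 10·log₁₀(1/S)` dB.

   0 dB means the therapy state is indistinguishable from rest; larger
   values mean a stronger therapy-induced deviation. The `1e-6` clamp on
   `S` caps the biomarker at 60 dB for pathological (antipodal) embeddings.

## Design choices worth knowing about

**Contrastive-loss convention.** The published form of the pairwise loss
places the hinge on same-class pairs, which contradicts its stated intent
(pull positives together, push negatives beyond the margin). The default
here follows the intent — `½·Y·D² + ½·(1−Y)·max(0, m−D)²` with `Y = 1` for
same-class pairs — and `as_printed = TRUE` reproduces the literal formula.
Both are unit-tested.

**Similarity domain.** Plugging a raw Euclidean distance into
`10·log₁₀(1/·)` would make *identical* signals score infinitely, which is
the opposite of the biomarker's published behavior (identical ⇒ 0 dB). The
published numbers treat the argument as a similarity with 1 = identical, so
the package defines `QB` on `S = 1 − D/2` of unit-normalized embeddings,
which reproduces that mapping exactly.

**Encoder.** No architecture is prescribed by the method, so the package
uses the smallest stack that trains quickly on a single CPU: three valid
convolution blocks (kernel 7, stride 2, channels 16/32/64, ReLU), global
average pooling, a linear projection to a 64-dimensional embedding, and L2
normalization. Forward and backward passes are written as plain matrix
operations; optimization is Adam (lr 1e-3, batch 32). The backward pass is
verified against numerical gradients in the test suite. Epochs fed to the
encoder are decimated from 512 to 128 Hz with an anti-aliasing filter —
content is band-limited to 60 Hz, so this is information-preserving while
shrinking the input four-fold. Pair/triplet sampling is uniform under the
configuration seed; hard-negative mining is deliberately out of scope.

**Reproducibility.** Every stochastic step (synthesis, sampling,
initialization, permutation draws) runs under an explicit seed through
`withr::with_seed`, so cohorts, fits and reports are bit-reproducible.
Subject `i`, phase index `p` of a cohort uses sub-seed
`master + 1000·i + p`, so any single recording can be regenerated alone.

## What the synthetic cohorts emulate — and what they do not

No public recordings accompany the method, so the package ships a
generator that reproduces the *statistical structure* the pipeline assumes:
a 1/f^a background (spectrally shaped white noise, default exponent 1),
five band-limited rhythm components (band-passed Gaussian noise, or pure
sinusoids for analytic tests), a poor-signal series that stabilizes after
0.5 s, and optional single-sample artifact spikes. The default rest profile
is alpha-dominant (δ 4, θ 3, α 6, β 2, γ 1 µV RMS, noise 2 µV); the default
therapy profile shifts power toward β/γ and suppresses α (δ 4, θ 3, α 3,
β 5, γ 3). The therapy profile is a *placeholder*: no quantitative
description of how the therapy alters band powers exists, so the defaults
encode a generic arousal signature chosen once and documented here.

Consequently, passing tests show that the pipeline *detects the band-power
structure it is given*, with correct arithmetic and reproducibility. They do
not show that real therapy sessions produce such structure, nor do they
reproduce any published cohort's similarity indices — those rest on
undeposited clinical recordings. Eye-blink and electromyographic artifacts
are modeled only as threshold-exceeding spikes; real artifact morphology,
non-stationarity within a phase, and inter-subject variability beyond seed
changes are not emulated.

## Numerical conventions and degenerate inputs

* Band integration is trapezoidal with interpolated points inserted at band
  edges, so the five band powers tile the broadband integral exactly;
  adjacent bands are half-open `[low, high)`, γ closed at 60 Hz.
* Welch defaults: 2 s Hann segments, 50% overlap — 0.5 Hz resolution at
  512 sps. The Parseval identity holds within 10% (window bias).
* Filters are zero-phase (forward–backward) Butterworth: band-pass order 4,
  notch order 2 with quality factor 30 (60 Hz default, 50 Hz configurable).
* A constant signal has zero fluctuations at every scale; its log-log curve
  is undefined, so the result is flagged degenerate rather than crashed on,
  and crossover detection refuses it explicitly.
* Zero residuals in crossover detection inherit the preceding sign, so a
  curve touching its reference line without crossing it counts no crossover.
* An epoch window longer than the recording yields an empty epoch table
  with a warning, not an error; an empty triplet batch scores loss 0 with a
  warning.

## Problem sizes used by the shipped checks

The test suite exercises unit behavior on 2-subject cohorts with 12–16 s
phases and 2–6 training epochs, which completes in about a minute. The
cohort-separation check runs the full protocol — 4 subjects, 60/300/60 s
phases, training on two subjects for 30 epochs and scoring the two held-out
subjects, with a 1000-permutation test on the rest-vs-rest versus
rest-vs-therapy similarity gap. These sizes were chosen so the whole suite
runs comfortably on a laptop CPU; larger cohorts only sharpen the
separation.

## A worked example

```{r example, eval = FALSE}
library(datbio)

cohort <- generate_cohort(cohort_spec(n_subjects = 4, seed = 20))
epochs <- prepare_training_epochs(cohort)

fit <- fit_siamese(epochs[epochs$subject %in% c("S01", "S02"), ],
                   mode = "triplet", config = train_config(epochs = 30, seed = 21))
pairs <- score_pairs(fit, epochs[epochs$subject %in% c("S03", "S04"), ])
cohort_report(pairs)
permutation_test_separation(pairs, n_perm = 1000, seed = 22)
```

On this seed the held-out rest-vs-rest pairs are markedly more similar than
rest-vs-therapy pairs, and the corresponding mean biomarker is larger for
rest-vs-therapy — the directional signature the method is designed to
detect. Both aggregation orders (mean of per-pair dB, and dB of the mean
similarity) are reported, because they differ whenever similarities vary
(Jensen's inequality); the mean of per-pair dB is the headline.

## Known limitations

* Single channel only; no montage handling, topography or connectivity.
* No ICA/regression artifact removal — only amplitude-threshold rejection.
* The EDF writer covers the minimal single-channel case (16-bit
  quantization documented); it does not write annotations or multi-signal
  files.
* Whether published crossover values are scale indices or crossing counts
  is not specified by the method's description; both modes are provided
  (`first_crossing`, `crossing_count`) and neither is asserted to be the
  original.
* Training is CPU-only by design; the encoder is intentionally small.
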