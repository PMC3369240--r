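---
title: "Subband sample entropy for sustained-vowel analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subband sample entropy for sustained-vowel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wpse)
```

## The analysis in one paragraph

A sustained vowel (/a/, about one second, 16 kHz) is trimmed of leading and
trailing non-voice, decomposed into a full binary wavelet-packet tree to
level 5 with an orthogonal Daubechies filter pair, and the sample entropy
of every node's coefficient sequence is computed, giving a
2 + 4 + 8 + 16 + 32 = 62-dimensional complexity profile whose keys are
physical frequency bands (250 Hz wide at level 5). Bands whose entropy
differs significantly between diagnostic groups (one-way ANOVA,
alpha = 0.05) feed a soft-margin RBF support-vector classifier
(C = 0.25, gamma = 0.0625), evaluated by stratified cross-validation.
Because the clinical recordings behind the method are not publicly
available, the package ships a seeded synthetic sustained-vowel generator
that reproduces the study conditions well enough to exercise and test
every stage end to end.

## Wavelet-packet decomposition

Each split convolves a node's sequence with a low-pass filter `h` and its
quadrature-mirror high-pass `g` and downsamples by two; both children are
split again, so level *j* holds 2^*j* equal-width subbands. The package
provides the Daubechies filters with 4, 6, 8 and 10 vanishing moments
(`db4` ... `db10`, 8-20 taps), normalised so `sum(h) = sqrt(2)`.

Two design points deserve a note:

* **Boundary handling is periodisation.** The transform is then an exactly
  orthogonal map: coefficient energy at every full level equals the signal
  energy (tested to 1e-6 relative; observed at rounding error), perfect
  reconstruction holds to ~1e-15, and node lengths halve exactly. The
  alternative, symmetric extension, is expansive: it duplicates boundary
  samples into extra coefficients, which both breaks the energy identity
  and injects duplicated material into the very sequences whose entropy
  we measure. Odd-length nodes are padded by repeating the final sample
  before a split; the pad is removed on reconstruction.
* **Sequency (frequency) ordering.** Downsampling folds the spectrum, so
  the natural (Paley) node order does not follow physical frequency. The
  permutation that does is the *inverse* Gray code of the natural index
  (prefix-XOR of its bits). We verified the mapping by brute force:
  a pure sine at the centre of each band of a level must put its maximum
  subband energy into the node the mapping labels with that band, and it
  does, for all bands at all levels tested. All reported features carry
  both indices; band keys (`L5_00250_00500`, level-major, zero-padded)
  name physical intervals in Hz.

A known limitation: the equivalent filters of a five-level iterated
Daubechies bank have substantial sidelobes, so although the *argmax* node
of a band-centre sine is always the correct band, the fraction of total
subband energy it captures ranges from 1.00 down to 0.586 (worst in the
3.75-4.25 kHz region, db10; shorter filters are worse). This is a property
of iterated short filter banks, not of the implementation — an independent
wavelet library returns identical energy fractions. Band-level features
therefore mix in some energy from spectral neighbours.

## Sample entropy

For a sequence of length *N*, embedding dimension *m* and tolerance *r*,
SampEn is `-ln(B_{m+1}(r) / B_m(r))` where `B_m` is the probability that
two distinct length-*m* epochs agree within *r* in Chebyshev distance.
Conventions, all tested against an independent brute-force double loop
with exact count equality:

* templates `i = 1..N-m` for both lengths (equal template counts);
* self-matches excluded; ties at exactly *r* count as matches;
* `r = r_frac * delta`, with `delta` the *population* SD of the exact
  sequence passed in. Scaling per coefficient sequence (rather than by the
  SD of the original audio) makes every subband's entropy invariant to the
  band's energy, so values are comparable across bands and the per-level
  normalisation constant of the filter bank cancels. A scale- and
  shift-invariance test asserts bitwise-equal match counts under
  power-of-two scaling.
* If no length-*m* or length-*(m+1)* pair matches, the statistic is
  undefined; the result is a tagged `NA` sentinel, never a cap. Downstream
  group statistics drop undefined cells bandwise; a silent cap would bias
  group means.

The optimised counting kernel (C++) sorts templates by first coordinate
and only compares pairs within *r* in that coordinate — an exact pruning,
not an approximation.

### Choosing m and r

The committed analysis uses `m = 2`, `r = 0.2`. The package reproduces the
standard sensitivity diagnostic on synthetic *group prototypes* (one voice
per group with every parameter at its profile mean, common f0 = 150 Hz):
entropy is non-increasing in *r* over 0.10-0.25 for every group's mean
curve, and the between-group spread of full-signal entropy is largest at
`m = 2` — under the committed generator profiles this holds across
arbitrary synthesis seeds, driven by the opposing m-dependence of the two
group contrasts (aspiration noise separates more at higher m; the
deficient groups' larger cycle-to-cycle perturbation erodes exactly the
longer-template contrast).

## The synthetic generator

`generate_voice()` is a source-filter synthesiser: a glottal pulse train
at f0 with per-cycle period jitter and amplitude shimmer, a cascade of
three second-order formant resonators (defaults are standard adult /a/:
730/90, 1090/110, 2440/170 Hz centre/bandwidth), additive Gaussian
aspiration noise scaled to the voiced RMS, peak normalisation, and
optional near-silence padding for endpoint-detection tests. All
randomness flows from the spec's seed; the caller's RNG state is left
untouched.

Group profiles (`group_profiles()`): aspiration noise is the primary
complexity driver — healthy 0.100, yin-deficient 0.030, qi-deficient
0.012 (fractions of voiced RMS) — because additive broadband noise
provably raises subband entropy, giving a controllable ground truth.
Jitter/shimmer run the other way (qi 6.0%/3.5%, yin 3.0%/2.5%, healthy
0.3%/1.5%), as in real dysphonic voices. These values were calibrated
once, jointly, so that the synthetic corpus reproduces the qualitative
clinical pattern (healthy above deficient in most bands; m = 2 maximal
separability; cross-validated accuracy in the >90% regime) and are
committed as the package defaults. `effect_size` interpolates every
group's mean *and spread* linearly toward the pooled values, so
`effect_size = 0` makes the three groups exchangeable — the basis of the
chance-level and type-I calibration checks.

What the generator does **not** emulate: prosodic drift, consonants,
room/channel effects, microphone response, inter-session variability, or
any physiological mechanism behind the clinical group differences. Passing
synthetic tests therefore demonstrates that the pipeline recovers a known
monotone complexity structure from audio — not that the clinical claims
replicate. The shipped reference table (`clinical_band_summaries()`)
preserves the published per-band summaries (47 significant bands, cohort
27/116/38) for bookkeeping and for checking the summary-statistics ANOVA,
but recomputing a one-way ANOVA from those printed summaries does not
generally reproduce the printed p-values, so the published test is treated
as unknown and is not an acceptance gate.

## Group screen and classifier

`compare_groups()` runs the classic equal-variance one-way ANOVA per band
(Kruskal-Wallis optional); `anova_from_summary()` computes the identical F
from group n/mean/SD alone via the sum-of-squares identity (tested to
1e-10 against ANOVAs on synthetically expanded raw data). Band selection
keeps p < alpha strictly, with no multiplicity correction by default
(mirroring the original analysis; Benjamini-Hochberg is available).

The classifier is a one-vs-one C-SVC with RBF kernel via libsvm (e1071),
with per-feature standardisation learned on the training data and stored
in the model. Grid search uses seeded stratified folds with ties broken
toward the smallest C then gamma, so results are reproducible
bit-for-bit. Models export to JSON; the restored model predicts through an
explicit implementation of the kernel decision function
`f(x) = sgn(sum_i y_i a_i* k(x_i, x) + b*)`, which doubles as an
independent check on libsvm's own predictions (tested for exact label
agreement).

**Evaluation protocol.** The pipeline's reported accuracy is stratified
k-fold cross-validation with the band screen re-run *inside every
training fold*. Screening once on all subjects and cross-validating only
the classifier inflates accuracy well above chance even on label-free
data (the screen has already seen the held-out subjects); with the nested
protocol, a zero-effect corpus scores at chance, which the tests assert.
The whole-data selection is still computed for presentation (it is what a
published band table reports). Folds whose screen selects nothing fall
back to all 62 bands so an accuracy is always defined. With the
imbalanced clinical composition (27/116/38) and the small committed
penalty C = 0.25, the classifier leans toward the majority class and
balanced-corpus accuracy is the cleaner recovery measure; the balanced
60/60/60 corpus at seed 42 is the committed end-to-end check.

## Numerical and degenerate-input choices

* Constant sequences: `r_frac * 0 = 0`, all epochs match exactly,
  SampEn = 0 (no special case needed; ties count as matches).
* Bands with zero within-group variance or fewer than two defined values
  in a group report `NA` p-values and are excluded from selection.
* Endpoint detection: double-threshold short-time energy (20 ms frames,
  10 ms hop, thresholds 10% / 2% of peak frame energy) grown through
  high-zero-crossing edge frames; an absolute energy floor (1e-6,
  assuming roughly unit-scale audio) turns all-silence input into an
  error instead of a spurious trim. The output is always a contiguous
  slice of the input.
* Batch extraction skips failing recordings with a message and records
  them in the `"skipped"` attribute rather than aborting a corpus run.

## Problem sizes used by the shipped checks

The test suite and the acceptance script were sized to run comfortably on
one CPU: filter-bank invariants use 100 seeded signals of length 4096
across the four wavelets; the entropy oracle uses 50 sequences of length
20-1000; the end-to-end check uses the balanced 60/60/60 one-second
corpus; the chance-level control uses twenty 45-subject half-second
corpora; the screen calibration uses 1000 replicate null bands at the
clinical group sizes. Full-corpus feature extraction runs at roughly
0.3 s per one-second subject.
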