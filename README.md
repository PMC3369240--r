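# wpse — subband sample entropy for voice-signal classification

`wpse` quantifies and classifies nonstationary biomedical voice signals,
specifically sustained-vowel (/a/) phonations recorded for diagnostic
auscultation. Dysphonic and healthy voices differ in how irregular their
energy is across frequency bands; this package measures that irregularity
band by band and turns it into a classifier:

1. **Endpoint detection** trims leading/trailing non-voice (double-threshold
   short-time energy with zero-crossing refinement).
2. **Wavelet-packet decomposition** (orthogonal Daubechies db4-db10,
   5 levels, periodised, frequency-ordered) splits the signal into
   2 + 4 + ... + 32 = 62 subbands; at 16 kHz the level-5 bands are 250 Hz
   wide, tiling 0-8 kHz.
3. **Sample entropy** of every node's coefficient sequence,
   `SampEn(m, r, N) = -ln(B_{m+1}(r) / B_m(r))` with `m = 2` and
   `r = 0.2 δ` (δ = the sequence's own SD), yields a 62-dimensional
   complexity profile per subject.
4. **Band screening** keeps the bands whose entropy differs between groups
   (one-way ANOVA, p < 0.05).
5. **Classification** is a one-vs-one C-SVC with RBF kernel
   `k(x, x') = exp(-γ‖x − x'‖²)` (C = 0.25, γ = 0.0625), evaluated by
   stratified cross-validation with the band screen nested inside each
   training fold.

Because no clinical recordings are distributed, the package includes a
seeded synthetic sustained-vowel generator (glottal pulse train with
jitter/shimmer → formant resonators → aspiration noise) with three
committed group profiles (healthy / qi-deficient / yin-deficient) whose
subband complexity differs by construction, so the entire pipeline is
reproducible and testable from code alone. The published per-band summary
statistics of the original 181-subject clinical cohort ship as reference
data (`clinical_band_summaries()`).

## Worked example

```r
library(wpse)

corpus   <- generate_corpus(c(healthy = 20, qi_deficiency = 20,
                              yin_deficiency = 20), seed = 42)
features <- batch_extract(corpus)                  # 60 x 62 feature table
stats    <- compare_groups(features)               # per-band ANOVA
selection <- select_features(stats, alpha = 0.05)
selection
#> <feature_selection> 47 band(s) at alpha = 0.05 (correction: none)

run <- run_pipeline(wpse_config(n_per_group = c(healthy = 20,
                                                qi_deficiency = 20,
                                                yin_deficiency = 20),
                                seed = 42))
run$report
#> <svm_eval> overall accuracy 100.0%
#>   healthy: 100.0%
#>   qi_deficiency: 100.0%
#>   yin_deficiency: 100.0%
#>                 predicted
#> truth            healthy qi_deficiency yin_deficiency
#>   healthy             20             0              0
#>   qi_deficiency        0            20              0
#>   yin_deficiency      0              0             20
```

47 of the 62 bands pass the screen on this synthetic corpus, and the
nested-screen cross-validation classifies all 60 subjects correctly —
the synthetic analogue of the >90% accuracy regime reported clinically.
`plot_band_profiles(features, level = 4)` shows the driving structure:
healthy voices sit above the deficient groups in mean subband entropy
across most bands.

Single signals work too:

```r
sig <- generate_voice(voice_spec(f0 = 150, noise_level = 0.1, seed = 1))
sample_entropy(sig$samples, m = 2, r_frac = 0.2)$value
sampen_sweep(sig$samples, m_values = 1:3, r_fracs = c(0.1, 0.15, 0.2, 0.25))
```

## Documentation

The methods vignette (`vignettes/wpse-methods.Rmd`) documents the model,
the filter-bank and entropy conventions, the generator's committed group
profiles and what they do and do not emulate, the nested-screen
evaluation protocol, and known limitations.
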