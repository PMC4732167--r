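# gaitclass

Probabilistic classification of pathological gait from wearable inertial
sensors.

`gaitclass` is for researchers working on instrumented gait assessment who
want a tested, end-to-end reference pipeline for discriminating gait classes
— healthy elderly (EL), post-stroke/hemiparetic (PS) and Huntington-like
hyperkinetic (HD) — from three inertial measurement units (IMUs): one per
shank and one at the waist, sampled at 128 Hz with axes (VT, AP, ML).

The pipeline:

1. **Class-specific hidden Markov models.** Per class, a two-state HMM with
   states tied to the stance and swing phases, trained *supervised* from
   gold-standard foot-strike (FS) and toe-off (TO) annotations. Emissions
   are 3-mode diagonal-covariance Gaussian mixtures over seven channels
   derived from one shank plus the waist ML acceleration (sign-flipped for
   the left side). Log-likelihoods come from the scaled forward recursion;
   λ_c = (π, A, {w, μ, Σ}) per class c, and a passage is scored by
   log p(O₁..₂ₛ | λ_c).
2. **90-dimensional features + RBF SVM.** H1–H3: the three class
   log-likelihoods on the first 2 s; H4–H6: whole-passage log-likelihood
   differences (length-invariant); T1–T6 and F1–F6 per channel: mean, SD,
   variance, max, min, range, and periodogram-based dominant-frequency and
   power descriptors. The SVM (libSVM, one-vs-one) is tuned by a grid
   search over (C, γ) maximizing the **minimum class-specific accuracy**
   under subject-grouped inner cross-validation.
3. **Majority voting.** Per-passage votes pooled per subject (per side for
   PS subjects). Evaluation is leave-one-subject-out (LOSO) throughout.

Because the clinical recordings behind the original study design are not
publicly deposited, the package ships a synthetic cohort generator
(`generate_cohort()`) producing stride-locked template signals with
class-specific timing, variability and PS left/right asymmetry, with exact
FS/TO annotations — every stage of the pipeline is testable against it. See
the methods vignette (`vignettes/gait-classification-methods.Rmd`) for the
models, parameter meanings and design choices.

## Worked example

```r
library(gaitclass)

cfg <- cohort_config(n_subjects = c(EL = 4, PS = 4, HD = 4),
                     passages = c(3, 4), strides = c(3, 5), seed = 42)
ds <- generate_cohort(cfg)
print(ds)
#> <gait_dataset> 86 trial-sides, 12 subjects
#> labs
#> EL HD PS
#> 28 28 30

res <- loso_evaluate(ds, svm_cfg = svm_config(C_grid = 2^seq(-2, 14, 4),
                                              gamma_grid = 2^seq(-13, -1, 4)))
print(res$confusion$svm_full)        # per-passage, full 90-dim feature set
#>             EL PS HD
#>   EL        27  0  1
#>   PS-notimp  0 14  1
#>   PS-imp     0 14  1
#>   HD         0  2 26
#> overall accuracy: 94.2%

print(res$vote$svm_full$confusion)   # subject level, after majority voting
#>             EL PS HD
#>   EL         4  0  0
#>   PS-notimp  0  4  0
#>   PS-imp     0  4  0
#>   HD         0  0  4
#> overall accuracy: 100.0%
```

Rows are actual units (PS split into impaired / not-impaired side, as in the
clinical reporting convention), columns the predicted class; the per-passage
matrix counts (passage, side) pairs, the voted matrix counts voting units
(one per EL/HD subject, two per PS subject). `res$confusion` also contains
the `hmm_maxll`, `svm_hmm` and `svm_timefreq` streams, so the contribution
of each feature family can be compared.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/gaitclass.R simulate --out data/ --seed 42
Rscript inst/cli/gaitclass.R evaluate --data data/manifest.json --out results/
```

Datasets live on disk as one CSV per trial-side (columns
`shank_acc_vt, ..., waist_acc_ml`, one row per sample) plus a JSON manifest
with labels and 0-based FS/TO event indices; configs are JSON.

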