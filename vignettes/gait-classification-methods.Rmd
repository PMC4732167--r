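---
title: "Probabilistic gait classification from wearable inertial sensors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic gait classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gait disorders leave characteristic signatures in the signals of body-worn
inertial measurement units (IMUs): a hemiparetic walker loads the paretic limb
briefly and asymmetrically; a choreic walker shows large stride-to-stride
variability; a healthy elderly walker is slower than a young adult but regular
and symmetric. `gaitclass` implements a probabilistic pipeline that classifies
short walking trials ("passages") into three such classes — healthy elderly
(EL), post-stroke (PS) and Huntington-like (HD) — from three IMUs: one on each
shank and one at the waist, each providing tri-axial acceleration and (at the
shanks) tri-axial angular velocity at 128 Hz, with axes fixed to vertical
(VT), antero-posterior (AP) and medio-lateral (ML).

The pipeline has three stages:

1. **Class-specific hidden Markov models.** For each class, a two-state HMM —
   states paired to the stance and swing phases of the gait cycle — is
   trained *supervised*, using gold-standard foot-strike (FS) and toe-off
   (TO) annotations to fix the hidden state sequence. Emissions are
   three-mode Gaussian mixtures over seven channels derived from one shank
   sensor plus the waist ML acceleration. The log-likelihood of a new
   passage under each class model measures how well that class's gait
   "signature" explains the data.
2. **A hybrid 90-dimensional feature set + RBF SVM.** The HMM
   log-likelihoods (and their pairwise differences) are combined with six
   time-domain and six frequency-domain descriptors per channel, and the
   resulting vectors are classified by a radial-basis-function support
   vector machine whose `(C, gamma)` are selected by a grid search
   maximizing the *minimum* class-specific accuracy.
3. **Majority voting.** Per-passage votes are pooled per subject (per side
   for PS subjects, where the impaired/non-impaired distinction is
   clinically relevant) and the plurality class wins.

Everything is validated by leave-one-subject-out (LOSO) cross-validation: no
recording of the tested subject ever contributes to HMM training, feature
normalization or SVM selection.

Because no patient recordings are distributed with the package, a synthetic
cohort generator provides labeled data with the statistical structure the
pipeline relies on; its scope and limits are discussed below.

## Preprocessing

All nine raw signals are low-pass filtered with a double-pass (zero-phase)
second-order Butterworth filter, cut-off 5 Hz: locomotor power in shank and
trunk signals sits below roughly 4 Hz, and the double pass preserves event
timing. Numerically, each pass starts from steady state at its first padded
sample, after odd-reflection padding of `3*(order+1)` samples; the effective
amplitude response is the squared single-pass magnitude, which attenuates a
30 Hz tone at 128 Hz sampling by about 3.4e-4. The filter, not the feature
code, is the single place where bandwidth decisions live; frequency-domain
features are computed on the *filtered* channels, consistent with every other
stage seeing filtered data. This matters only above 5 Hz, where filtered
spectra carry essentially no power.

## The HMM engine

**Observation channels** (fixed order): shank ML angular velocity and its
approximated derivative, shank AP acceleration and its approximated
derivative, approximated derivatives of the shank ML and VT accelerations,
and waist ML acceleration. The waist ML channel is sign-flipped for left-side
trials so lateral sway has the same polarity regardless of which shank
supplies the other six channels. Derivatives are forward first differences
scaled by the sampling rate, with the last value repeated to preserve length;
at gait frequencies the first-difference error is O(f/fs) and negligible
after 5 Hz filtering.

**Topology.** Gait is periodic, so a strict left-right (feed-forward) chain
cannot represent more than one stride. The package therefore uses an ergodic
2x2 transition matrix estimated from the annotated state sequence by simple
counting; stance->swing->stance cycling emerges from the counts themselves,
with self-transition probabilities near `1 - 1/(phase duration in samples)`.
The initial distribution is the empirical distribution of first-sample
states.

**State labeling.** Stance is the half-open interval [FS, TO), swing
[TO, next FS); samples before the first and after the last event extend the
adjacent phase. Indices are 1-based in memory and 0-based in the on-disk
JSON.

**Emission model.** Per state, a three-mode Gaussian mixture with diagonal
covariances, fitted by EM on the pooled frames of that state across all
training trials (pooling, rather than per-trial fitting, uses every frame and
keeps the estimator simple; the number of EM problems per LOSO fold is two
per class). Numerical choices: k-means initialization on a subsample of at
most 8192 frames (fixed internal seed, so training is deterministic), at most
200 EM iterations, relative log-likelihood tolerance 1e-6, and a variance
floor of 1e-6 times each channel's pooled variance, which prevents component
collapse on near-degenerate channels.

**Likelihood evaluation** uses the scaled forward recursion (per-step
normalization in the style of Rabiner's classic tutorial), implemented in
C++, with two cross-checks kept in the package and exercised by the tests: a
pure-R log-sum-exp forward recursion and a scaled backward recursion must
agree with it, and on short sequences all must match exhaustive enumeration
over all state paths. Classification by maximum log-likelihood evaluates the
*first 2 s* of each passage (256 samples at 128 Hz) so that passages of
different length are compared over a common window; ties break
deterministically in the fixed class order EL, PS, HD.

## The feature set

Ninety features per (passage, side):

* **H1–H3**: log-likelihoods under the EL, PS and HD models on the first 2-s
  window. The window restriction is applied to all three (the likelihood of
  a longer passage is not comparable to that of a shorter one).
* **H4–H6**: pairwise differences EL−PS, EL−HD, PS−HD of log-likelihoods
  computed on the *whole* passage. Differencing cancels the length
  dependence, so these capture relative model fit over all available data.
  H4 − H5 + H6 = 0 identically; the redundancy is deliberate, mirroring the
  original feature design, and harmless to an SVM.
* **T1–T6 per channel** (42): mean, standard deviation, variance, maximum,
  minimum, range.
* **F1–F6 per channel** (42): from the raw (untapered) periodogram of the
  mean-removed channel: power at the first dominant frequency (F1), power at
  the second dominant frequency (F2), the two frequencies themselves (F3,
  F4), total power over (0, fs/2] (F5), and the ratio F1/F5 (F6).

Two frequency-domain conventions are package decisions, since no formulas
accompany the original feature list: the spectrum estimator is the plain
periodogram of the demeaned signal (simplest defensible choice; a Hann taper
changes peak powers but not peak locations at gait SNRs), and the "second
dominant frequency" is the highest *local* maximum at least 0.2 Hz away from
the global one — without the separation rule the shoulder bin of the main
peak would almost always win. DC is excluded everywhere (the mean is removed
before the transform). A constant channel has an empty spectrum; the six
features are returned as zeros with a warning rather than NaNs.

## SVM and model selection

The classifier is libSVM's C-SVC with an RBF kernel (one-vs-one multiclass).
Features are z-scored with statistics computed on the training partition
only. Classes are weighted inversely to their training counts (normalized to
mean one): a C-SVC's implicit prior follows the class counts, and under
leave-one-subject-out validation every fold depletes exactly the held-out
subject's class, which on an uninformative problem drags accuracy
systematically *below* chance. Balancing the misclassification costs removes
that prior shift; on separable cohorts it is practically inert, and it is
consistent in spirit with selecting hyper-parameters by minimum class
accuracy. The grid search scores every `(C, gamma)` pair by subject-grouped,
class-stratified k-fold cross-validation *within the training set* (default
k = 5) and selects the pair maximizing the minimum class-specific accuracy —
with three unbalanced classes, optimizing overall accuracy would happily
sacrifice the smallest class. Ties prefer smaller C, then smaller gamma
(flatter decision functions). The default grids are the customary coarse
exponential grids `C = 2^-5..2^15`, `gamma = 2^-15..2^3` in steps of 2^2;
the LOSO-scale examples and the acceptance script use a thinned 5x4 subgrid
(steps of 2^4), which costs a fraction of the fits and, on the synthetic
cohorts, selects models of indistinguishable accuracy.

## Voting and evaluation conventions

Each (passage, side) prediction is one vote. EL and HD subjects pool both
sides into a single poll; PS subjects get one poll per side, because
impaired- and non-impaired-side gait genuinely differ. Note that the
*construction of voting units* uses the true group label (whether a subject's
sides are pooled depends on whether they are PS); this follows the original
evaluation design and is an evaluation convention, not an inference-time
capability. Vote ties fall back to the subject's pooled counts across both
sides, then to the fixed class order. Confusion matrices report PS split by
side (rows EL, PS-not-impaired, PS-impaired, HD) against the three predicted
classes; accuracy counts a PS row as correct when PS is predicted.

`loso_evaluate()` returns four prediction streams — max-likelihood HMM,
SVM on HMM features only, SVM on time/frequency features only, SVM on the
full set — before and after voting, so the contribution of each feature
family can be compared. Holding out subject *s* only changes the HMM of
*s*'s own class, so the implementation trains each distinct leave-one-out
model once and caches per-trial log-likelihoods; results are identical to
the naive per-fold retraining, only cheaper.

## The synthetic cohort generator

The generator emulates the *structure* the pipeline exploits, not
biomechanics. Per channel, a stride is a sum of two to four Gaussian bumps
placed at fixed fractions of stance and swing (heel-strike transient,
push-off, swing peak), time-warped to per-stride stance/swing durations and
scaled by class-, subject- and stride-level amplitude factors; white sensor
noise is added *before* the 5 Hz filter, and FS/TO indices are recorded
exactly from the construction. Durations are sampled from normals truncated
at ±3 SD (no negative durations); each stride duration in samples is
`round(fs * t)`, so a zero-variance configuration yields exactly periodic
events.

Defaults follow the study conditions the framework targets: 10 EL / 15 PS /
17 HD subjects, 2–16 passages per subject and 2–7 strides per passage per
foot (means near 9 and 4.5), 128 Hz. Class timing parameters encode the
orderings reported in the clinical gait literature — EL regular (stride time
1.05 s, CV 3%), PS slow (1.40 s) with an impaired side whose stance fraction
is 12% longer and whose shank ML angular velocity is attenuated to 55%, HD
with the largest stride-time CV (15%) and amplitude jitter (25%). The exact
amplitude scales are package choices: no per-channel signal statistics exist
to copy, so they were fixed once at values that make the three classes
separable without being trivially so at the single-stride level.

What passing tests on this cohort do **not** show: robustness to real sensor
artifacts (drift, misalignment, soft-tissue resonance), to imperfect event
annotation, or to the overlap of real clinical populations. The synthetic
classes are, by construction, separable; end-to-end accuracies on them are
upper bounds of a sanity-check kind, not estimates of clinical performance.
Two structural controls partially compensate: with identical class
parameters and no subject heterogeneity, LOSO accuracy must not *exceed*
chance (that would indicate an information leak somewhere in the pipeline),
and voting must not degrade a per-passage accuracy above one half.

A subtlety worth stating plainly: under such a null, leave-one-subject-out
accuracy of a flexible classifier does not center exactly on 1/3 — it sits
slightly *below* it. Any learner that fits its training sample pulls its
decision boundary toward the training points; removing the held-out
subject therefore biases the model away from that subject's region, and
the effect grows with the dimensionality of the feature stream (in null
simulations here, the 6-feature SVM stream is statistically at chance
while the 84- and 90-feature streams sit 3–5 points below it). This
"removal bias" is a property of holdout validation itself, vanishes as
cohorts grow, and is the opposite direction of leakage; the package's
chance-control test applies the two-sided binomial band around 1/3 to a
pooled multi-cohort stream and is expected to flag the low side at shipped
cohort sizes.

The chance-level control deliberately uses *equal* class sizes and no
between-subject variability: with unbalanced classes an uninformative
classifier drifts toward the majority class, and subject-level random
effects cluster the predictions, inflating the variance of the accuracy
estimate beyond its nominal binomial band; both would make the control test
a test of something other than label–feature independence. Even so,
predictions within a subject (and within a fold, which shares retrained
models) remain correlated, so a *single* cohort's accuracy is
over-dispersed relative to a binomial draw; the shipped control therefore
pools the prediction streams of five independently generated cohorts before
applying the band.

## Problem sizes

The shipped examples, tests and the acceptance script run the full-roster
cohort at 3–6 passages per subject and 3–6 strides per passage (about 390
trial-sides — incidentally the size of the original study — with LOSO
completing in a few minutes), the ablation-ordering replicates on twenty
independent 4/4/4-subject cohorts, and the chance control on a 6/6/6
cohort. Parameter-recovery checks use ~500 strides per class, at which point
empirical transition frequencies are accurate to ~0.001.

## Known limitations

* The left and right trials of one passage are generated (and modeled) as
  independent; real bilateral gait is phase-locked.
* The emission GMM uses diagonal covariances; correlated channels (e.g. a
  derivative and its parent) are modeled only through the mixture.
* The per-side HMM treats each side as a separate data source; a coupled
  two-chain model would be the natural extension.
* The pipeline assumes gold-standard FS/TO annotations at training time;
  sensitivity to annotation jitter is untested.
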