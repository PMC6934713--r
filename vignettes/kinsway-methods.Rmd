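---
title: "Methods: classifying whole-body movement and postural sway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying whole-body movement and postural sway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsway)
```

## The problem

Youth on the autism spectrum show broad motor differences — more variable,
more irregular whole-body movement and postural sway — relative to typically
developing (TD) peers. `kinsway` implements an analysis pipeline that asks
whether those differences are large and consistent enough to classify
individual participants from markerless kinematic recordings made during a
balance videogame: 3D positions of 20 skeleton joints from a depth camera
plus the 2D centre of pressure from a balance board, 62 channels in all,
recorded while each participant holds each of 10 static balance poses over
several training sessions.

Because the motivating study's participant recordings are not publicly
released, the package ships a synthetic cohort generator that reproduces the
*statistical structure* the analysis relies on. Everything downstream of the
generator — cleaning, features, classifier, evaluation, interpretation — is
the reusable analysis and treats its input as arbitrary recordings in the
documented format.

## Pipeline

1. **Cleaning** (`clean_dataset()`): per channel, forward-fill the rare
   missing samples; apply a level-5 Haar discrete wavelet transform and keep
   only the approximation (lowpass) component, removing the high-frequency
   sensor noise a human body cannot produce; trim long series to their
   centred window to drop non-task movement at the edges; then, per pose,
   discard whole files whose channel variances are extreme outliers under a
   fitted exponential distribution (equipment malfunction).
2. **Features** (`featurize_dataset()`): slide a window of 20 samples with
   shift 10 along the cleaned series and compute, per window, the Shannon
   entropy and the variance of each channel — a 124-dimensional feature
   vector per window (2 x 62). Recordings of different lengths contribute
   different numbers of vectors but always 124 columns.
3. **Classifier** (`movement_ensemble()`): one random forest of 10
   bootstrap-trained CART trees per pose, each forest trained only on its
   pose's vectors. A participant is classified hierarchically: each vector
   votes via its forest score, the vectors of a pose are combined by
   majority vote into a partial decision, and the partial decisions are
   combined by a second majority vote into the final label. The mean pose
   probability, rescaled from $[0,1]$ to $[-1,+1]$ as $d = 2p - 1$, is the
   participant's *boundary distance* — the continuous output correlated
   with covariates.
4. **Evaluation** (`run_cv()`): stratified 5-fold cross-validation at the
   participant level (all of a participant's recordings stay on one side of
   the split), with precision, recall, specificity, MCC and F1 per fold and
   as unweighted fold means. Two differential experiments are wired in:
   dropping all z (depth) channels (`xy_only`, 84 features), and balancing
   the groups by subsampling the larger one (`balance_n`).
5. **Interpretation** (`total_mdi()`, `effect_size_report()`,
   `correlate_distance()`): per-forest mean-decrease-impurity importances,
   normalized to sum to one within each forest and summed across the 10
   forests (totals in $[0, 10]$); fold-to-fold overlap of top-20 lists;
   Cohen's d group effect sizes on per-participant mean feature values; and
   Pearson/Spearman correlations of boundary distance with age, motor and
   symptom covariates.

## The synthetic cohort

Each participant carries a latent motor-severity variable $s \ge 0$,
gamma-distributed with mean 1 (ASD) or 0.15 (TD). Covariates are monotone
functions of $s$ plus noise: the BOT-2 motor percentile decreases in $s$,
the SRS-2 and RBS-R symptom scores increase in $s$; IQ and sex have
group-specific distributions matching the cohort the study describes
(ASD IQ 104 +/- 15 vs TD 112 +/- 10; 95% vs 74% male).

Each channel of a recording is

$$x_t = \mathrm{drift}_t + a_t + \varepsilon_t,$$

with three ingredients chosen to be the *minimal* model exhibiting the
phenomena the cleaning pipeline targets:

* **drift**: a mixture of three sinusoids below 0.4 Hz with random
  frequency, phase and amplitude (0.2-0.6) — slow postural wander, common
  to both groups;
* **sway noise** $a_t$: AR(1) with coefficient $\phi = 0.98$ at 30 Hz
  (about a 1.7 s time constant), i.e. slow enough to survive the level-5
  lowpass, with stationary standard deviation
  $$\sigma = \sigma_{base}\,\bigl(1 + \beta\, s\, \mathbb{1}[\text{channel
  affected}]\bigr)\, f(\text{age, group});$$
* **jitter** $\varepsilon_t$: white Gaussian noise (SD 0.3) standing in for
  the high-frequency tracking artifacts the wavelet stage removes.

The group effect therefore lives in the *variance* (and consequently the
spread-sensitive features) of an affected channel subset — by default the
head, both shoulders, both feet and the two board channels, 17 of 62. The
age factor $f = 1 + 0.05\,(18 - \text{age}^*)$ makes younger participants
noisier, and the ASD effective age $\text{age}^*$ lags by 3 years,
emulating a developmental motor delay: young TD participants resemble the
ASD group, which is why boundary distance correlates negatively with age.

Missing samples occur independently per cell with probability $10^{-4}$,
and whole files are corrupted (all channel variances multiplied by $10^4$)
with probability 0.01. Corruption is kept rare deliberately: the QC stage
fits its exponential distribution on *all* files of a pose in a single pass
(no refit after discards), so a heavy corrupt mass would inflate the fitted
mean and cost recall; at a 1% rate the corrupt files sit far beyond the
$10^{-7}$-tail threshold while clean files never reach it. The resulting
discard rate (~1%) is the generator's own property, not a calibration to
any real-data rate.

Default study conditions: 20 ASD + 20 TD participants, sessions 2-4, 10
poses, 1600-2400 raw frames per recording at 30 Hz, $\beta = 2$. Every
random quantity derives from one master seed; each recording's stream is
seeded by hashing (seed, participant, pose, session), so files are
independently reproducible.

### What the generator does not emulate

No skeletal geometry or biomechanical constraints (channels are
statistically, not anatomically, coupled); no pose-specific movement
shapes; no session/learning effects; no distributional-shape group
differences beyond variance inflation, so the entropy features carry only
weak signal here even though both feature families are computed and
ranked. Passing recovery tests on this cohort therefore demonstrates that
the pipeline detects variance/spread group structure of realistic
magnitude under realistic artifacts — not that it would achieve any
particular accuracy on real Kinect/balance-board data.

## Numerical and design choices

* **Denoised series = approximation coefficients.** The wavelet stage
  returns the decimated level-L approximation (block means after the
  $2^{-L/2}$ rescale), not a full-length reconstruction, because the
  downstream windowing (20 samples ~ tens of seconds) only makes sense on
  a decimated series. Odd lengths use half-sample symmetric padding (the
  last sample is repeated), so each level maps $T \to \lceil T/2 \rceil$.
  The effective frame rate becomes $30/2^5 \approx 0.94$ Hz.
* **Trimming after decimation**, with the 10,000-sample cap counted in
  post-wavelet samples, following the stage order of the pipeline; at
  default synthetic lengths the cap never binds and is exercised by its
  own unit tests.
* **Leading missing values** are back-filled from the first valid value
  (forward fill has nothing to propagate there).
* **Variances are population variances** (divide by $n$) everywhere — QC
  and features — for internal consistency.
* **Entropy estimator**: histogram Shannon entropy over B = 10 equal-width
  bins spanning the window's own range, natural log. It is shift- and
  scale-invariant and bounded in $[0, \ln B]$; a zero-range window has
  entropy 0.
* **Forest score**: each tree contributes its predicted class (its leaf's
  majority vote), so a forest's score for a vector is the fraction of its
  trees voting ASD. Tree-growing settings (10 trees, Gini, unbounded
  depth, minimum leaf size 5, $\lfloor\sqrt{p}\rfloor$ candidate features
  per split, bootstrap resampling) follow standard random-forest practice
  and are exposed via `forest_params()` and recorded in the fitted model.
* **Ties go to ASD at every level** (a vector score of exactly 0.5 votes
  ASD; split votes at pose and participant level resolve to ASD). The
  rule is explicit and testable, and biases toward sensitivity. One
  consequence worth knowing: on pure-noise inputs the bias cascades —
  most vectors, hence most poses, hence essentially all participants come
  out ASD — so chance-level performance typically manifests as a
  degenerate confusion table whose MCC is 0 by the 0/0 convention rather
  than as values scattered around 0.
* **Participant probability** $p$ is the unweighted mean over available
  poses of the mean vector score; a vote-fraction alternative is available
  (`prob_method = "vote_fraction"`). Poses whose files were all discarded
  are silently omitted from both the vote and $p$.
* **MDI normalization**: importances are normalized to sum to 1 within
  each forest before summing across forests, so totals lie in
  $[0, \text{n poses}]$ — the scale on which the headline rankings are
  reported.
* **Cohen's d on per-participant means**: feature values are averaged
  over a participant's windows before the group comparison, avoiding
  pseudo-replication from correlated windows.
* **0/0 metric convention = 0** keeps degenerate folds comparable.

## Problem sizes used by the tests

The test suite exercises the full default conditions (20+20 participants,
sessions 2-4, 10 poses; about 1,200 recordings per run) across ten seeds
for the parameter-recovery checks, and a reduced null configuration
(8+8 participants, one session, zero effect) for chance-level calibration;
unit tests run on purpose-built small fixtures generated in code. These
sizes are the package's chosen verification conditions and complete in a
few minutes on a single CPU.

## Known limitations

* The synthetic effect size is chosen to make group structure recoverable
  with realistic overlap; it is not calibrated to reproduce any real
  cohort's accuracy numbers, which depend on unreleased data.
* Forest probabilities are uncalibrated vote fractions; the boundary
  distance is a ranking score, not a posterior probability.
* With 10 trees per forest the score granularity is 0.1, which makes the
  tie rules consequential (see above).
* The QC stage assumes at least two files per pose and, being single-pass,
  tolerates only a small corrupt fraction before losing recall.
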