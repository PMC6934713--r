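# kinsway

Classification of whole-body movement and postural sway timeseries.

`kinsway` is an R implementation of a complete digital-phenotyping
pipeline for distinguishing youth with autism spectrum disorder (ASD)
from typically developing (TD) youth using markerless whole-body
kinematics and balance-board postural sway recorded during static balance
poses. It is aimed at movement scientists and methodologists who want a
tested, reproducible version of this analysis that runs end-to-end on
synthetic cohorts with known ground truth.

Each recording is a `T x 62` timeseries: 3D positions of 20 skeleton
joints plus the 2D centre of pressure, for one (participant, session,
pose). The pipeline:

1. **Cleaning** — forward-fill imputation, level-5 Haar wavelet
   denoising (keeping the decimated lowpass approximation), middle
   trimming, and pose-wise exponential-tail variance QC that discards
   files with variances beyond the `1e-7` tail of a fitted exponential.
2. **Features** — sliding windows (size 20, shift 10); per window, the
   histogram Shannon entropy and the population variance of each channel:
   a 124-dimensional feature vector (2 × 62).
3. **Classifier** — an ensemble of 10 pose-specific random forests (10
   CART trees each). Hierarchical majority voting: vectors → pose partial
   decision → participant label, ties to ASD. The mean pose probability
   `p`, rescaled to `d = 2p − 1 ∈ [−1, +1]`, is the participant's
   *boundary distance*.
4. **Evaluation** — stratified participant-level 5-fold CV with
   precision, recall, specificity, MCC
   (`(TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`) and F1, plus two
   differential experiments: dropping the depth (z) channels, and
   balanced-group subsampling.
5. **Interpretation** — total mean-decrease-impurity feature rankings
   (per-forest normalized, summed over the 10 forests), fold-consistency
   overlap of top-20 lists, Cohen's d group effect sizes on
   per-participant feature means, and Pearson/Spearman correlations of
   boundary distance with age, motor and symptom covariates.

Because no public recording set exists for this paradigm, the package
includes a first-class synthetic cohort simulator
(`simulation_config()`, `simulate_dataset()`, `generate_dataset()`)
whose recordings carry the statistical structure the analysis assumes:
group- and age-dependent sway-noise variance, slow drift, white sensor
jitter, rare missing values, and occasional whole-file corruption. See
the methods vignette (`vignettes/kinsway-methods.Rmd`) for the model and
all design choices.

## Worked example

```r
library(kinsway)

# Default study conditions: 20 ASD + 20 TD participants, sessions 2-4,
# 10 poses (~1,200 recordings), group effect beta = 2.
report <- run_pipeline(simulation_config(), seed = 1)
print(report$cv)
```

```
<movement_cv> stratified 5-fold cross-validation
 fold  precision     recall specificity  mcc   f1
    1 1.00 (3/3) 0.75 (3/4)  1.00 (4/4) 0.77 0.86
    2 1.00 (4/4) 1.00 (4/4)  1.00 (4/4) 1.00 1.00
    3 0.67 (4/6) 1.00 (4/4)  0.50 (2/4) 0.58 0.80
    4 1.00 (2/2) 0.50 (2/4)  1.00 (4/4) 0.58 0.67
    5 1.00 (4/4) 1.00 (4/4)  1.00 (4/4) 1.00 1.00
Average: precision 0.93, recall 0.85, specificity 0.90, mcc 0.79, f1 0.86
```

Each fold row shows the held-out confusion as `metric (count/total)` with
ASD as the positive class; the `Average` row is the unweighted fold mean.
The rest of the report carries the interpretation outputs:

```r
head(report$ranking, 3)        # total normalized MDI, scale [0, 10]
#                feature total_mdi
#  variance:shoulder_R:z 0.6333031
#      variance:foot_L:y 0.5787349
#      variance:foot_R:x 0.5726165

report$fold_overlap            # top-20 consistency across folds
# [1] 0.88

subset(report$correlations, covariate == "age_years")
#  covariate  pearson_r pearson_p  n
#  age_years -0.2087158 0.1961962 40
```

Here the top-ranked features come from the channels that carry the
injected group effect (shoulders, feet, head, board sway), younger
participants sit closer to the ASD side of the boundary (negative age
correlation), and symptom covariates correlate positively with boundary
distance — the qualitative pattern the method is designed to expose.

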