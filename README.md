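# emgatrophy

Surface electromyography (sEMG) analysis for a concrete clinical question:
after a limb fracture, is muscular atrophy caused by **peripheral nerve
injury** or by **limb immobilization** (disuse)? The two causes need
different rehabilitation, and the standard bedside electrodiagnostic —
needle EMG — is invasive. This package implements the full non-invasive
analysis chain on which an sEMG-based answer rests, together with
synthetic-data generators that reproduce the statistical structure of the
two study protocols it emulates (an evoked-response experiment on rats and
a maximum-voluntary-contraction experiment on patients), with ground truth
at every stage.

The chain is:

1. **Simulation** — voluntary-contraction sEMG as superposed motor-unit
   action potential trains, and electrically evoked compound-response
   trains (2 mA, 2 Hz, 100 µs, 30 s protocol) with per-epoch true latency,
   peak-to-peak amplitude, duration and area under the curve. Nerve injury
   is encoded as motor-unit loss with slowed conduction, immobilization as
   per-unit amplitude reduction.
2. **Preprocessing** — canonical channel ordering, 50 Hz IIR notch
   (Q = 30), fourth-order Butterworth 20–500 Hz band-pass, zero-phase by
   default.
3. **Evoked analysis** — stimulus-artifact detection (8 × MAD threshold),
   epoch segmentation, extraction of the four clinical parameters, and
   unpaired Welch t-tests between groups. Nerve injury shows smaller
   amplitude, shorter duration, smaller AUC and longer latency.
4. **Features** — per-window RMS, iEMG, ARV, median frequency (MDF) and
   mean power frequency (MPF) on 0.5 s windows with 1/8 overlap over a
   stable segment, ratio-normalized against the unaffected limb (patients)
   or the pre-surgery healthy baseline (rats).
5. **Classification** — gradient-boosted trees, RBF SVM and k-nearest
   neighbours with small hyperparameter grids, 80/20 splits and stratified
   5-fold cross-validation, reporting
   `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `specificity = TN/(TN+FP)` and
   `sensitivity = TP/(TP+FN)` with positive = immobilization.

## Worked example

Evoked group comparison (50 epochs per condition) followed by a small
rat-protocol classification experiment:

```r
library(emgatrophy)

st <- stimulus_config(train_duration = 25)            # 2 Hz -> 50 epochs
nerve <- simulate_evoked_train(condition_params("nerve_injury"), st, seed = 1)
immob <- simulate_evoked_train(condition_params("immobilization"), st, seed = 2)
p_nerve <- extract_evoked_train(nerve$record, st)
p_immob <- extract_evoked_train(immob$record, st)
print(compare_groups(p_nerve, p_immob), digits = 3)
#>      parameter mean_a  sd_a mean_b  sd_b     t        p significant
#> 1   latency_ms   6.94 0.310   5.01 0.309  31.1 1.35e-52        TRUE
#> 2 amplitude_mv   4.11 0.401   6.28 0.758 -17.9 1.01e-28        TRUE
#> 3  duration_ms   7.13 0.339  10.17 0.505 -35.3 7.81e-53        TRUE
#> 4     auc_mvms   8.84 1.004  19.90 2.559 -28.4 6.31e-38        TRUE

cohort <- generate_rat_cohort(cohort_config("rat_evoked",
  groups = list(immobilization = 3, nerve_injury = 3),
  acquisitions_per_subject = 20), seed = 7)
features <- rat_feature_table(cohort)                  # 120 ratio rows
cv <- run_cv(features, k_folds = 5, classifier_spec("gbdt"), seed = 8)
compute_metrics(cv$confusion)
#> accuracy 98.33%, specificity 98.33%, sensitivity 98.33% (n = 120)
```

The comparison table reads: group A (nerve injury) has a ~2 ms longer
latency and roughly 35% smaller amplitude, 30% shorter duration and 55%
smaller rectified area than group B (immobilization), each difference
significant at p < 0.05 — the expected electrodiagnostic signature. The
metrics line is the pooled cross-validated confusion matrix of the
gradient-boosted model on the acquisition-level feature ratios.

The end-to-end pipeline (simulate → preprocess → features → normalize →
classify, with a provenance block and deterministic reports) is available
as `run_pipeline(pipeline_config(...))`.

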