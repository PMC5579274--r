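# radrisk

Radiomic feature extraction and imbalance-adjusted outcome modelling for 3D
PET/CT tumour imaging.

Radiomics quantifies intratumoural heterogeneity by extracting large
batteries of features from medical images and relating them to clinical
endpoints — here, tumour-failure outcomes (locoregional recurrence, distant
metastases, death) in head-and-neck cancer, where event rates of 10–20%
make naive classifiers useless at the decision threshold. `radrisk` is
aimed at quantitative-imaging researchers who need the full pipeline —
image processing, feature definitions, feature selection, imbalance-aware
learning and prognostic evaluation — as reproducible, tested code that runs
end-to-end on synthetic data with known ground truth.

## What it computes

**Feature battery (1615 per modality).** From a 3D volume (SUV for PET, HU
for CT) and an aligned binary ROI mask:

- 10 first-order intensity features (variance, skewness, kurtosis, SUVmax,
  SUVpeak, SUVmean, AUC of the cumulative intensity–volume histogram, total
  lesion glycolysis, % inactive volume, generalized effective total uptake);
- 5 shape features (volume, maximum diameter, solidity, eccentricity,
  compactness);
- 40 texture features — 9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM — computed at
  each of 40 extraction settings (isotropic voxel size ∈ {1,…,5} mm ×
  {Uniform, EqualProbability} quantization × {8, 16, 32, 64} gray levels).

Texture matrices are built once per scan over the 13 merged directions of
3D space (26-connectivity), with diagonal neighbours distance-corrected by
inverse Euclidean distance (1, 1/√2, 1/√3) and diagonal run lengths
accumulating their geometric step length.

**Imbalance-adjusted learning.** Each bootstrap training sample with N⁻
majority and N⁺ minority instances is split into P = round(N⁻/N⁺) balanced
partitions (minority copied into every partition, majority divided without
replacement; e.g. N⁻ = 168, N⁺ = 32 → five partitions, two with 33 and
three with 34 majority instances). Logistic models average coefficients
across partitions and across 100 bootstraps; random forests grow one tree
per partition, with minority under/oversampling weights w ∈ {0.5, …, 2.0}
tuned by stratified sub-sampling (10 splits, 2:1).

**Feature selection.** Reduction to 25 candidates by the Gain criterion
(0.5·|Spearman r_s| + 0.5·(1 − max MIC to the selected set)), then forward
selection over model orders 1–10 maximizing the 0.632+ bootstrap AUC

    AUC_632+ = (1 − w)·AUC_app + w·max(AUC_oob, 0.5),
    w = 0.632 / (1 − 0.368·R),  R = (AUC_app − AUC'_oob)/(AUC_app − 0.5)

**Evaluation.** AUC / sensitivity / specificity / accuracy at threshold
0.5, DeLong tests, Harrell's concordance index, Kaplan–Meier log-rank
stratification into two risk groups (prob > 0.5) or three (1/3, 2/3).

## Worked example

```r
library(radrisk)

# a synthetic FDG-PET tumour phantom: 24^3 grid, ellipsoidal ROI,
# heterogeneity correlation length 2 mm
ph <- make_phantom(rng_seed = 7)
features <- extract_battery(ph$vol, ph$mask)
length(features)
#> [1] 1615
round(features[c("SUVmax", "SUVmean", "volume", "compactness")], 3)
#>      SUVmax     SUVmean      volume compactness
#>      18.802       4.778       3.016       0.055

# an imbalanced cohort (n = 194, ~15% events) with a known 3-feature
# signal among 27 noise features, plus an independent test cohort
train <- make_cohort(rng_seed = 1)
test  <- make_cohort(rng_seed = 2)
test$patient_id <- sub("P", "T", test$patient_id)
table(train$event)
#>   0   1
#> 166  28

cfg <- radrisk_config(master_seed = 1, target_size = 10, max_order = 3,
                      n_boot = 20)
bundle <- run_train(train, features = c("sig1", "sig2", "sig3",
                                        sprintf("noise%02d", 1:27)),
                    config = cfg)
bundle$logistic$features
#> [1] "sig1" "sig3" "sig2"      # the planted signal, recovered at order 3

ev <- run_evaluate(bundle, test)
round(unlist(ev$logistic$metrics), 3)
#>         auc sensitivity specificity    accuracy
#>       0.911       0.903       0.724       0.753
round(ev$logistic$concordance, 3)
#> [1] 0.918
```

The AUC of 0.91 on the untouched test cohort is the out-of-sample
discrimination of the recovered three-feature model; the concordance of
0.92 says the same risk scores also order the (censored) event times. With
`clinical = c("age", "hn_type", "n_stage")` the bundle additionally trains
a partition-ensemble forest and `run_evaluate()` reports its risk-group
stratification and Kaplan–Meier log-rank p-values.

A thin CLI wraps the same functions for shell use
(`exec/radrisk simulate|extract|univariate|train|evaluate`), reading and
writing NIfTI volumes and CSV tables.

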