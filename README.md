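# mmsurv — multimodal ensemble survival modelling

`mmsurv` is an R framework for building cancer-prognosis models from several
data modalities at once — a clinical table, omics feature matrices (mRNA,
miRNA, methylation-style values), and whole-slide images represented as bags
of patch embeddings — and combining them by **late fusion of risk scores**.
It is aimed at biostatisticians and computational-pathology researchers who
want a complete, testable reference implementation of this workflow that
runs on a laptop with synthetic data.

## What it implements

* **Per-modality risk models.** For each tabular modality, a Cox
  proportional-hazards model built by *iterative forward feature selection*:
  a fitted/replayable preprocessing chain (missingness filter at 20%, median
  imputation, one-hot coding, z-scoring, greedy Spearman deduplication at
  |rho| > 0.8), a univariate screen over 10 random 80/20 sub-partitions of
  the training fold (keep features with mean validation C-index > 0.5), and
  greedy forward selection that accepts a feature only when it strictly
  improves mean validation C-index, up to 20 features. For the image
  modality, an **attention-based multiple-instance deep Cox model**:
  per-patch projection (256-d) → ReLU/dropout → multi-head self-attention
  with a Nyström low-rank approximation → average pooling → linear risk
  head, trained with the average negative log partial likelihood (Breslow),
  Adam (lr 0.001), risk-score accumulation across patients, and plateau
  learning-rate decay.

* **Late fusion.** Per endpoint, fused risk
  `r_i = Σ_m w_m r_{i,m}` with validation-performance weights
  `w_m = p_m_val / Σ p_val` (plus a uniform-weight variant).

* **Censoring-aware evaluation.** Harrell's C-index with 1000-replicate
  bootstrap CIs and Welch comparison of bootstrap distributions,
  median-risk stratification with Kaplan–Meier curves and the log-rank
  test, and 1/3/5-year AUROC with DeLong variance, CIs and the paired
  DeLong test — all computed on test predictions pooled across a 5-fold
  cross-validation.

* **Synthetic multimodal cohorts** (`simulate_cohort()`): proportional-
  hazards outcomes with calibrated censoring, two coupled endpoints
  (DFS ≤ OS), sparse informative features with correlated nuisance
  features, and embedding bags whose signature-patch fraction is a sigmoid
  function of the planted risk — so every stage has a ground-truth recovery
  test with no external data.

* **A WSI preprocessing path** (`segment_tissue()`, `extract_patches()`,
  `encode_patches()`): saturation-threshold tissue masking, 512×512
  patching, and a pluggable patch-encoder interface with a deterministic
  toy encoder for tests. Pretrained pathology foundation models are out of
  scope by design; any encoder function can be plugged in.

## Worked example

```r
library(mmsurv)

sim <- simulate_cohort(simulation_config(
  n_patients = 120,
  modalities = list(
    clinical = list(n_features = 8,  n_informative = 2, beta = c(1.0,  0.7), rho = 0.1),
    omics    = list(n_features = 12, n_informative = 2, beta = c(0.8, -0.6), rho = 0.3)),
  censoring_target = 0.3, seed = 42))

res <- run_experiment(sim$bundle,
                      run_config(endpoints = "OS", n_folds = 5, seed = 7,
                                 bootstrap_B = 200, horizons = 36))
print(res)
```

```
<experiment_result> 120 patients, 5 folds, seed 7
  OS:
    clinical       C-index 0.722 (0.670, 0.769)
    omics          C-index 0.576 (0.516, 0.635)
    fused          C-index 0.749 (0.692, 0.789)
    fused_uniform  C-index 0.753 (0.694, 0.796)
```

The clinical model dominates (its two planted effects are strongest), the
omics model adds weaker independent signal, and the weighted ensemble beats
both single-modality models. The per-fold fusion weights average 0.538
(clinical) / 0.462 (omics) — proportional to each modality's validation
C-index. Downstream metrics come from the same report object: the ensemble's
3-year AUROC is 0.866 and its median-risk split separates survival curves at
log-rank chi-square 61.7 (p ≈ 4e-15).

A command-line front end over the same functions lives in
`inst/cli/mmsurv.R` (`simulate` and `run-all` subcommands).

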