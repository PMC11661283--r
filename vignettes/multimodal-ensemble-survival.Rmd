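---
title: "Multimodal ensemble survival modelling with mmsurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal ensemble survival modelling with mmsurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

`mmsurv` implements a late-fusion workflow for predicting censored survival
outcomes (overall survival, OS, and disease-free survival, DFS, both in
months) from several data modalities at once: a clinical feature table,
one or more omics feature matrices (mRNA, miRNA, methylation-style
continuous values), and histopathology whole-slide images represented as
bags of patch embeddings. One risk model is trained per modality and per
endpoint; their scalar risk scores are combined afterwards. Late fusion
keeps each model small — an important guard against overfitting when the
cohort has a few hundred patients but tens of thousands of omics features —
and lets each modality use the architecture that suits it.

All models are built on the Cox proportional-hazards assumption: patient
$i$'s hazard is $h_0(t)\exp(\eta_i)$ with a shared baseline $h_0$ and a
time-invariant log-partial-hazard (risk score) $\eta_i$. Because every
modality's model is fitted on the same cohort, the baselines coincide, which
is the justification for fusing the raw risk scores linearly:

$$ r_i = \sum_{m=1}^{M} w_m\, r_{i,m}, \qquad
   w_m = \frac{p_m^{\mathrm{val}}}{\sum_{m'=1}^{M} p_{m'}^{\mathrm{val}}}, $$

where $p_m^{\mathrm{val}}$ is modality $m$'s validation C-index. A
uniform-weight variant ($w_m = 1/M$) is provided for comparison. Whether any
per-modality standardization should precede the sum is a genuinely open
point: scores from a forward-selection Cox model and from a deep model need
not live on the same scale even when the baseline hazard is shared. We fuse
raw scores by default for fidelity to the weighting scheme above and expose
`standardize = TRUE` as an explicit switch.

## Tabular modalities: forward-selection Cox

Preprocessing is a fitted, replayable transformer (`preprocess_fit()` /
`preprocess_apply()`): features missing in more than 20% of patients are
dropped (strictly greater; a feature missing exactly 20% survives),
remaining gaps are filled with training-cohort medians, categorical columns
are one-hot coded, numeric columns are z-scored with training statistics,
and near-duplicate features are removed by a greedy scan that drops any
column whose absolute Spearman correlation with a previously kept column
exceeds 0.8. Decisions a user should know about:

* **One-hot uses k−1 indicators** with the modal level as reference. Full
  one-hot would make the Cox design exactly collinear; the reference-level
  convention is the standard fix and changes nothing about the fitted
  risks.
* **Deduplication runs after encoding**, in the column order of the input
  table ("previous features" = earlier columns). The scan order is the only
  tie-break and is deterministic by construction. Absolute correlation is
  used because an anticorrelated duplicate is exactly as redundant as a
  correlated one; `signed = TRUE` restores the literal one-sided rule.
* **z-scores use the sample sd** (denominator $n-1$); `sd_type =
  "population"` is available. Constant columns are dropped.

Model construction (`univariate_screen()`, `forward_select()`) follows an
iterative forward-selection-while-fitting scheme. Ten random 80/20
sub-partitions of the training fold are drawn once and reused. Screening
fits a univariate Cox model per feature on each sub-training set and
averages Harrell's C-index over the matching sub-validation sets; features
pass iff the mean exceeds 0.5. The forward pass starts from the top-ranked
feature and, per iteration, tries every remaining candidate alongside the
current set, accepting the best candidate only on strict improvement of the
mean validation C-index, up to 20 features (roughly one-tenth of a
several-hundred-patient training fold). The best mean validation C-index
becomes $p_m^{\mathrm{val}}$. Further choices:

* Cox fits use Efron tie handling and an optional mild ridge penalty
  (default $10^{-6}$) purely for numerical stability with near-collinear
  omics columns; set `penalty = 0` for an unpenalized fit. At this
  magnitude the two agree to several decimal places.
* A fit that fails or returns non-finite coefficients scores 0.5
  ("uninformative") for that sub-partition instead of aborting the scan.
* Exact ties between candidates resolve in favour of the higher screening
  rank, making the whole procedure bit-reproducible under a master seed.
* The final model is refit on the full training fold with the selected set
  (the sub-train fits exist only to score candidates).

## The bag modality: attention-MIL deep Cox

A slide is a bag of patch embeddings (`n_patches × d`), produced either by
an external pretrained encoder or by this package's image path:
saturation-threshold tissue masking (Otsu by default) with median blur and
morphological closing, tiling into contiguous 512×512 level-0 patches kept
at ≥ 50% tissue coverage, downsampling each patch to 224×224 and applying a
pluggable encoder. Pretrained pathology encoders are deliberately out of
scope; `toy_encoder()` (seeded random projection of per-channel summary
statistics) provides a deterministic stand-in so the whole path runs
without network access or slide files, directly on in-memory RGB arrays.

The risk model (`train_deep_cph()`) scores a bag by: linear projection of
each embedding to 256 dimensions, ReLU and dropout (0.25), multi-head
self-attention (8 heads) to mix information across patches, average pooling
over patches, and a linear head producing the scalar risk. Pooling makes
the network size-agnostic, so training can subsample large bags (up to 4096
patches per step) while testing uses full bags. Attention uses a Nyström
low-rank approximation: `m` landmark tokens are formed as segment means,
the full softmax kernel is reconstructed from two thin kernels and an
iteratively approximated Moore–Penrose pseudo-inverse of the m×m landmark
kernel. Numerical choices:

* **Landmarks** default to 256; bags smaller than the landmark count fall
  back to exact attention (the approximation only pays off beyond that
  size, and the fallback is exact rather than approximate).
* **Pseudo-inverse iterations** default to 18 Newton–Schulz steps — enough
  that with landmarks = tokens the module reproduces exact attention to
  ~1e-3 and better; the commonly seen setting of 6 steps is not converged
  on typical softmax kernels and silently degrades the kernel.
* The pseudo-inverse initial scaling constant is treated as a stop-gradient;
  the iterates themselves are differentiated.

Training minimizes the average negative log partial likelihood (Breslow
ties),
$$ \mathcal{L} = -\tfrac{1}{n_{\mathrm{ev}}}\sum_{i:\,\delta_i=1}
   \Big[ r_i - \log\!\!\sum_{j:\,t_j \ge t_i}\!\! e^{r_j} \Big], $$
with Adam at learning rate 0.001, up to 100 epochs, and plateau decay
(×0.1 after 5 epochs without internal-validation improvement). A Cox loss
over a single patient is undefined — the partial likelihood needs
cross-patient risk sets — so bags are scored one at a time ("batch size 1")
while risk scores accumulate over 32 patients before the loss is computed
and backpropagated through all of their tapes. This accumulation contract
is a design decision of this package, standard in MIL survival practice;
an epoch-level loss would be the main alternative and would change only the
gradient frequency. The internal validation split (20%, stratified by
event) exists solely to drive the scheduler and to report the modality's
$p^{\mathrm{val}}$.

The network and its gradients are implemented on a small tape-based
reverse-mode autodiff core written for this package (R has no established
deep-learning runtime in this stack); gradient correctness is enforced in
the test suite by central finite differences through both attention paths,
and the loss gradient closed form is checked the same way.

## Evaluation

Five-fold cross-validation with random fold assignment (stratification by
event is available but off by default, matching plain random splitting).
Per fold, every fitted statistic — preprocessing medians and z-scores,
screening, selection, fusion weights — is computed from the training side
only; test-fold predictions are pooled across folds into a single vector
per model before any metric is computed. Metrics:

* **Harrell's C-index** over comparable pairs (earlier time is an event);
  risk ties count 0.5; pairs tied in time are not comparable. 95% CIs from
  1000 patient-level bootstrap replicates (percentile method); bootstrap
  replicate vectors from two models are compared with Welch's t-test.
* **Median-risk stratification**: high-risk iff risk strictly exceeds the
  cohort median (ties at the median go low-risk, documented
  determinism); groups are compared by Kaplan–Meier curves and the
  two-group log-rank test.
* **Time-specific AUROC** at 1, 3 and 5 years: patients censored before the
  horizon are excluded, events at or before the horizon are positives,
  everyone else negative. AUC is the Mann–Whitney statistic; variance and
  CIs via DeLong's structural components; a paired DeLong test compares
  correlated ROC curves.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage has a recovery-style test
with known ground truth. It emulates the *structure* of a multimodal
cohort: AR(1)-correlated Gaussian features with a sparse informative
subset; event times from an exponential-baseline proportional-hazards model
(inverse sampling, baseline hazard 0.02/month so median survival at
$\eta=0$ is about 35 months); independent exponential censoring whose rate
is calibrated by bisection to a target censored fraction (default 30%);
a DFS endpoint coupled to OS as `dfs = os × Beta(4, 2)` so recurrence never
follows death; and embedding bags mixing background and signature
Gaussians where the expected signature-patch fraction is
`plogis(2 × risk)` — the bag carries the risk signal only through patch
composition, as in attention-MIL's assumptions. Default cohort size is 226.

What it does **not** emulate: real mRNA/methylation marginal distributions
(counts, zero inflation, batch effects), informative censoring, non-PH
effects, or spatial structure within slides. Passing tests therefore
demonstrate that the machinery recovers planted signal under its own model
assumptions — not that any particular performance level will transfer to
real cohorts.

## Problem sizes used by the test suite and the acceptance script

Chosen to exercise every code path at desk scale: metric oracles on 100
random instances of n ≤ 50; Cox recovery at n = 1000 over 10 seeds;
forward-selection recovery at n = 500 with 50 features over 10 seeds; deep
training on 200 bags of 50–200 patches (d = 32, projection width 32,
30 epochs) with a permuted-label negative control; the end-to-end
cross-validated ensemble on a 150-patient cohort with small bag and
network settings. The acceptance script mirrors the last configuration and
additionally reports coefficient recovery, selection recall, and the
Nyström-vs-exact deviation.

## Known limitations

* No time-dependent (inverse-probability-weighted) C-index or AUC; the
  horizon exclusion scheme is simple and slightly optimistic under heavy
  censoring.
* No learned (stacked) fusion; weights are a fixed function of validation
  performance.
* Interval censoring, competing risks and date arithmetic are out of scope;
  times are months as reals.
* The deep model trains on CPU via the package's own autodiff; it is meant
  for moderate bags and cohort sizes, not for foundation-model-scale
  training.
* Embedding bags are stored in a plain-text directory layout (manifest +
  one TSV per patient) chosen for exact round-trips and zero binary
  dependencies.
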