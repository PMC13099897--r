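# wsimil

Multiple-instance learning (MIL) pipelines for three-tier recurrence-risk
stratification of H&E-stained whole-slide images (WSIs).

In HR+/HER2− early breast cancer, the 21-gene recurrence score (RS, an
integer 0–100 from a genomic assay) is the clinical standard for grading
recurrence risk into low / medium / high tiers that guide chemotherapy
decisions. The assay is expensive; routine histology is not. `wsimil`
implements, as tested and reusable R code, the full computational stack for
predicting the RS-derived risk tier directly from a slide:

1. **Tissue segmentation and patching** — Gaussian blur, HSV saturation
   channel (optionally boosted by its morphological gradient), Otsu
   thresholding, morphological cleaning, and extraction of a non-overlapping
   256×256 level-0 patch grid with a tissue-coverage criterion.
2. **Feature bags** — a pluggable patch-encoder interface turns each slide
   into a "bag": an N×D matrix of patch-instance features plus coordinates.
   Deterministic stub encoders make the whole stack runnable offline;
   pathology foundation encoders plug in behind the same interface.
3. **Three slide classifiers**, written from scratch with hand-derived
   reverse-mode gradients (validated against finite differences in the test
   suite) and an Adam optimizer:
   - a single-branch clustering-constrained attention model with gated
     attention `A = σ(W_b h + b_b) ⊙ tanh(W_a h + b_a)`, a 384-dim attention
     space, a GELU two-layer 512→256 classifier head, module-wise dropout,
     and a composite bag + instance-clustering loss;
   - a gated multi-head attention model (8 heads) with class-specific
     attention distributions, three-branch aggregation, and a bottleneck
     classifier with per-class readout;
   - an attention-pooling + gradient-boosted-tree pipeline: a tanh attention
     network pools a slide embedding `S = Σ aᵢ xᵢ`, a 23-dimensional
     enhanced feature vector (MIL logits/probabilities, attention
     statistics, patch count, distribution descriptors) feeds an XGBoost
     head (200 trees, η = 0.1, depth 6).
4. **Imbalance-aware losses** — focal loss
   `FL(p_t) = −α_t (1−p_t)^γ log p_t` with a medium-class weight α = 3,
   label smoothing `y' = (1−ε) y + ε/K` with ε = 0.1, weighted
   cross-entropy, and exact/tanh GELU.
5. **Patient-level stratified 5-fold cross-validation** with linear
   learning-rate warmup, early stopping, per-class
   precision/recall/F1, macro one-vs-rest AUC, and mean ± SD fold
   aggregation; plus the non-MIL majority-vote patch baseline.
6. **Attention heatmaps** — min-max-normalised scores painted over patch
   footprints, Gaussian-smoothed or bilinearly upsampled, jet-colormapped
   and alpha-blended over the slide.
7. **A synthetic generator** for class-conditional feature bags (default
   priors 0.45/0.10/0.45 reproduce a 210-case cohort with exactly 21
   medium-tier cases) and toy stained-slide images with exact ground-truth
   masks.

Everything is tibble-first: manifests, fold tables, metric reports and
feature tables flow through dplyr/tidyr, and fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(wsimil)

# a synthetic 150-case cohort with the study's class imbalance
gen   <- generate_bags(synth_bag_config(
  n_cases = 150, class_priors = c(0.45, 0.10, 0.45), dim = 64,
  signal_fraction = 0.3, effect_size = 2, seed = 11))
folds <- make_folds(gen$truth[, c("case_id", "tier")], k = 5, seed = 1)

cv <- run_cv(gen$bags, folds, kind = "clam_sb",
             config = train_config(lr = 5e-4, max_epochs = 30,
                                   warmup_epochs = 5,
                                   early_stop_patience = 8,
                                   loss_kind = "focal",
                                   alpha = c(1, 3, 1), gamma = 2,
                                   epsilon = 0.1, seed = 1),
             model_config = clam_config(input_dim = 64,
                                        encoder_hidden = 128,
                                        attn_hidden = 64,
                                        cls_hidden = 64,
                                        dropout = 0.25))
glance(cv)
#> # A tibble: 8 × 3
#>   metric            mean      sd
#>   <chr>            <dbl>   <dbl>
#> 1 accuracy         0.986 0.0308
#> 2 auc              0.998 0.00382
#> 3 macro_precision  0.973 0.0596
#> # …
```

The summary says the gated-attention model, cross-validated at the patient
level, recovers the planted class structure: mean held-out accuracy 0.986
and macro one-vs-rest AUC 0.998 across the five folds (SDs in the second
column). For comparison, the non-MIL majority-vote patch baseline
(`run_cv(..., kind = "baseline")`) reaches mean accuracy 0.853 on the same
folds — the gap is what instance-level attention aggregation buys.

Per-fold and per-class views come from the tidiers:

```r
tidy(cv)                      # one row per fold
tidy(cv$fold_metrics[[1]])    # per-class precision/recall/F1/AUC
autoplot(cv$fits[[1]])        # training curves
```

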