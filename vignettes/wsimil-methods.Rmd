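---
title: "Methods: attention-based MIL for whole-slide risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-based MIL for whole-slide risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wsimil)
```

## The problem and the modeling frame

A whole-slide image is a gigapixel scan of a stained tissue section. Its
clinical label here — a three-tier recurrence-risk class derived from the
21-gene recurrence score (RS) — attaches to the *slide*, not to any
individual region. Multiple-instance learning (MIL) is the natural frame:
the slide is a *bag*, its tissue patches are unlabeled *instances*, and an
attention mechanism learns which instances carry the label-relevant
morphology. All three classifiers in `wsimil` share this structure and are
permutation invariant in the instances by construction (weighted sums under
softmax weights); the test suite asserts this invariance at $10^{-6}$ for
bags of size 1, 2 and 100.

The label itself comes from `rs_to_tier()`: RS $\le 15$ is low, 16–25
medium, $\ge 26$ high for premenopausal node-negative patients. The
guidelines print only the chemotherapy decision boundary at RS 26 for the
other two patient groups, so the package applies the same interior 15/25
split there by default — a deliberate choice so that a three-tier label
always exists — and exposes every cut-off as configuration. When a manifest
supplies both an RS and a tier, the tier wins; disagreement with the mapping
is a warning by default and an error under strict mode, because curated
tiers occasionally encode clinical context the bare score does not.

## Preprocessing

Tissue is separated from glass background on a low-magnification level
(target downsample 32×, selected by the standard
best-level-for-downsample rule): Gaussian blur (σ = 2 px at the working
level), RGB→HSV, saturation channel. Stained tissue is chromatic and the
background nearly achromatic, so saturation gives the cleanest bimodal
histogram. The binarisation threshold is Otsu's exhaustive
between-class-variance maximisation over a 256-bin histogram — implemented
in-package and cross-checked in the tests against a literal loop over all
thresholds. A *morphological-gradient enhancement* (dilation − erosion of
the saturation channel with a disc of radius 2, added to the channel and
clipped) is on by default: it boosts saturation at tissue boundaries before
thresholding. Because the enhancement is a modeling choice rather than a
mathematical necessity, a flag disables it, and with the flag off the
pipeline is plain Otsu on the blurred saturation channel.

Cleaning removes connected components below 1000 px² and fills holes below
500 px² at the working level; closing uses a radius-2 disc. None of these
scales is canonical — they are package defaults sized for typical 32×
working levels and all configurable. A level-0 patch of 256×256 px enters
the grid iff at least half of its footprint is tissue
(`tissue_coverage_min = 0.5`); truncated edge patches are dropped rather
than padded, so every bag instance sees identical geometry. Coordinates are
0-based `(x, y)` top-left corners with half-open footprints.

## Feature bags and encoders

Patch encoders are pluggable: anything that maps a batch of RGB patches to
a fixed-dimension feature matrix, deterministically for fixed weights,
satisfies the interface. Production use would plug a pathology foundation
encoder in here; the package ships two deterministic stubs
(`identity_stats`: per-channel mean/SD, an oracle checkable against raw
pixels; `seeded_projection`: a fixed random linear map of downsampled
pixels) so that every downstream stage is testable offline. Bag row order
is defined by grid order alone — batching is an implementation detail, and
a test encodes the same grid at batch sizes 1 and 4 and requires identical
matrices.

Bags persist as single-file serialized containers (features snapped to
single precision, matching the fidelity of typical embedding stores, plus
coordinates and case attributes) behind `write_bag()`/`read_bag()`.

## The classifiers

**Gated-attention single-branch model (`clam_sb`).** Per-instance encoder
$D \to 512$ with GELU and dropout; gated attention
$A = \sigma(W_b h + b_b) \odot \tanh(W_a h + b_a)$ in a 384-dim space;
softmax over instances; attention-weighted pooling to a 512-dim slide
vector; a two-layer GELU classifier with 512→256 reduction. Dropout
(default 0.4) is applied independently to the encoder output, the gated
attention product, and the classifier hidden layer. The bag loss is
soft-target focal loss (below); an auxiliary *instance-clustering* loss
pseudo-labels the `k_sample = 8` most-attended instances positive and the 8
least-attended negative and scores a small binary instance classifier on
them with cross-entropy; the composite objective weighs the two equally
(`bag_weight = 0.5`). A "B = 8" setting is sometimes described as a head
count, but a single-branch model has no natural slot for attention heads;
the reading consistent with the instance-vs-bag loss balance is the
clustering sample size, which is what the package implements (an optional
multi-head attention variant remains possible behind the same config).

**Gated multi-head class-attention model (`abmil`).** Eight parallel heads;
each projects instances to a 512-dim head space, forms
$\tanh \odot \sigma$ gated activations in a 256-dim attention space, and
maps them linearly to one score per class. Head scores merge by elementwise
mean (a concat-then-linear merge is available behind a flag; the mean is
the default because it keeps the per-head score scale independent of the
head count). A column-wise softmax turns the merged $N \times K$ scores
into one attention distribution per class; class-specific bag vectors
$V_c = \sum_i W_{ic} x_i$ pass through a shared GELU bottleneck
($D \to 512$) and a *diagonal* per-class readout — class $c$'s logit reads
only its own branch, respecting the branches' class-specific construction
(the concatenated-readout variant exists behind the same merge flag). The
mean sigmoid-gate activation is recorded per epoch as telemetry; it is
reported, not asserted, since gate openness is an empirical observation,
not a contract.

**Attention pooling + boosted trees (`milboost`).** A plain tanh attention
network (no gate — deliberately simpler than the gated form) scores
instances; the softmax-weighted sum $S = \sum_i a_i x_i$ is the slide
embedding, and a linear head on $S$ supplies MIL logits, trained with focal
loss. The boosted stage consumes a **23-dimensional enhanced feature
vector** that has no canonical enumeration in the literature;
the package's fixed order — 3 MIL logits, 3 MIL probabilities,
$\log(1+N)$, ten attention statistics (mean, SD, min, max, median, Shannon
entropy, entropy$/\log N$ with the $N = 1$ case defined as 0, Gini, top-1
weight, top-5 mass) and six distribution descriptors (skewness, excess
kurtosis, 25th/75th percentiles, IQR, fraction above the mean) — is this
package's normative reconstruction, chosen to cover every named category
and total exactly 23. By default the boosted head sees the 23-vector alone;
a flag-free alternative is simply passing `cbind(S, features)` to
`fit_boosted()`, which accepts any feature matrix. The boosted model is
XGBoost with the multiclass softmax objective, 200 trees, learning rate
0.1, depth 6, leaf penalty $\gamma = 0$ and leaf-weight penalty
$\lambda = 1$.

## Losses

Focal loss $\mathrm{FL}(p_t) = -\alpha_t (1-p_t)^\gamma \log p_t$
down-weights easy examples; the default class weights $(1, 3, 1)$ put
triple weight on the medium tier, which is 10% of the cohort. The focusing
exponent is nowhere printed in the source settings; the package defaults to
the canonical $\gamma = 2$. Label smoothing
$y' = (1-\varepsilon) y + \varepsilon/K$ with $\varepsilon = 0.1$, $K = 3$
improves calibration. The two compose as *soft-target focal loss*
$\sum_c y'_c \cdot [-\alpha_c (1-p_c)^\gamma \log p_c]$ — a definition
chosen so that $\varepsilon = 0$ recovers plain focal loss and $\gamma = 0$
recovers smoothed weighted cross-entropy; the $\gamma = 0$ identity is
property-tested on 1000 random simplex points. Probabilities are clamped to
$[10^{-7}, 1-10^{-7}]$ before any logarithm.

GELU is provided exactly as $x\,\Phi(x)$ and as the tanh approximation;
the two agree within $10^{-3}$ on $[-5, 5]$ (asserted on a 0.01 grid).

## Training and evaluation

All gradients are hand-derived reverse-mode passes over plain matrices —
there is no autodiff dependency — and every model's analytic gradient is
checked against central finite differences at tolerance $10^{-4}$ in the
tests. Optimisation is Adam with L2 regularisation added to the gradient
(coefficient $10^{-4}$), one bag per step, linear learning-rate warmup over
5 epochs, early stopping on validation loss (patience 20 for the
gated-attention model, shorter for faster-converging models; the checkpoint
returned is the best-validation-loss epoch, the criterion chosen because
validation loss is the quantity early stopping monitors). Published base
rates: $3\times10^{-5}$ / 100 epochs for the single-branch model,
$4\times10^{-4}$ / 20 epochs for the multi-head model. Training is fully
seeded: the same seed reproduces the history bitwise.

Cross-validation is stratified at the patient level: cases are shuffled
within tier and dealt round-robin, so fold class counts differ by at most
one and no case ever appears on both sides of a split (asserted on every
generated fold). Metrics follow the standard multiclass conventions:
per-class precision/recall/F1 (F1 = 0 when P + R = 0), macro and
support-weighted averages, and — since the multiclass AUC definition was
open — macro-averaged one-vs-rest ROC AUC on predicted probabilities,
computed via `pROC` and independently cross-checked against a
rank-statistic (Wilcoxon) oracle in the tests. Fold aggregation reports the
arithmetic mean and *sample* SD (denominator $n-1$); only the means are
treated as checkable arithmetic, since SD conventions vary across
reporting styles. Ties in argmax resolve to the lowest class index, as does the
majority vote of the non-MIL baseline, in which a multinomial logistic
patch classifier (every instance inheriting its bag's tier) votes per
slide.

## The synthetic generator

`generate_bags()` produces the statistical structure the MIL models assume:
tiers by stratified largest-remainder allocation over priors
$(0.45, 0.10, 0.45)$ — at 210 cases, exactly 21 medium-tier cases, the
cohort imbalance the losses are designed around; bag sizes uniform on
30–80; background instances $\mathcal N(0, I)$; signal instances
$\mathcal N(\mu_c, I)$ for a fraction (default 0.3) of each bag, with
$\mu_c$ = effect size (default 2) times fixed orthonormal directions from a
seeded QR decomposition, giving equal pairwise class separations. An
optional grey-zone mode places the medium-tier mean midway between the low
and high means to mimic the intermediate biology of medium-risk cases; it
is off by default because the default geometry is the cleaner test of model
capacity.

What the generator does *not* emulate: stain variation, scanner domain
shift, spatial correlation between neighbouring patches, heterogeneous
per-slide signal fractions, and any real morphology. Passing the recovery
criteria therefore demonstrates that the implementations can learn
attention-mediated bag structure under the cohort's imbalance — not that
they reach any particular performance on real slides.

Problem sizes: the cross-validated recovery runs use 150 cases at $D = 64$
with a reduced-width model (encoder 128, attention 64, classifier 64,
dropout 0.25, Adam at $5\times10^{-4}$, ≤ 30 epochs with patience 8) —
widths and rates sized to the 64-dim synthetic bags, where the full
1024-dim defaults would be badly over-parameterised. The pipeline smoke
configuration is smaller still (tens of cases, 3 epochs, 3 folds).

## Heatmaps

Attention scores are min-max normalised per slide and painted over patch
footprints at a render scale (default 1/32), then either Gaussian-smoothed
(the package's separable convolution uses reflective padding, which
conserves the mass of interior blobs to within 1%) or bilinearly upsampled
from the patch lattice — the latter path is the one used for per-class
attention maps. Degenerate normalisations are fixed by convention: all-equal
scores render at the neutral 0.5, and a single-patch slide renders its lone
footprint at 1.0 against a 0 background so the signal stays visible. The
jet colormap is alpha-blended (default α = 0.4) over the downsampled slide.
Rendering is deterministic; heat values are clamped to $[0, 1]$.

## Known limitations

- The per-bag training loop is single-threaded R; it is sized for
  desk-scale experiments and hundreds of cases, not thousand-slide cohorts.
- Pyramidal slide decoding is out of scope: slides enter as in-memory
  rasters (any reader that yields an RGB array works), and the
  level-selection rule assumes the caller knows the pyramid's downsamples.
- The 23-feature vector is a reconstruction; columns are named and ordered
  stably so downstream consumers can rely on them, but other
  reconstructions of the same categories are possible.
- Real-slide performance claims are outside what the synthetic suite can
  establish, as discussed above.
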