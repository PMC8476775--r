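---
title: "Confidence-aware multilabel IHC classification with ihctriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-aware multilabel IHC classification with ihctriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Immunohistochemistry (IHC) stains a protein of interest brown (DAB) over a
blue hematoxylin counterstain. In testis sections, eight cell types can be
scored — five germ-cell stages arranged as concentric layers of the
seminiferous tubule (spermatogonia at the periphery through preleptotene,
pachytene, round/early and elongated/late spermatids toward the lumen) and
three somatic types (Sertoli cells threading the germ layers, interstitial
Leydig cells, and the thin peritubular rim). An image may express the
protein in any subset of the eight, so the task is multilabel: one sigmoid
per cell type, none of them mutually exclusive.

Manual annotation is slow and error-prone; a classifier is only useful for
replacing it if each prediction comes with a trustworthy confidence, so
that confident predictions can be auto-accepted and the rest routed to a
human. `ihctriage` implements that complete workflow: a hybrid Bayesian
network (HBNet), Monte-Carlo Drop-Weights inference, and the DHC confidence
score that ranks predictions for triage.

## Model

### Features

Two feature streams are concatenated into a hybrid vector:

* **Learned features.** A convolutional trunk (3x3 same-padded
  convolutions + ReLU, a 2x2 max pool per block) processes the RGB image;
  the final feature map is flattened — keeping the spatial layout, which
  matters because the germ-cell compartments are position-structured — and
  projected to a `cnn_feature_dim`-long vector. Two backbones are provided:
  `small_cnn` (3 blocks, 64 px input) for desk-scale work and `vgg19_like`
  (16 conv layers, 1024 px input) matching the reference scale; at that
  scale the projection reads the globally average-pooled 512-channel map
  instead of a flatten, whose weight matrix would be prohibitive.
* **Handcrafted features.** HOG (8 unsigned orientation bins, 8 px cells,
  8x8-cell blocks at one-cell stride, per-block L2 normalisation), the 13
  Haralick co-occurrence statistics averaged over the four directions, and
  the 7 log-scaled Hu moments, all computed on the Rec. 709 luminance
  channel. Each feature is z-scored with training statistics (the three
  families live on very different scales) and the block is reduced by PCA.
  The reference dimensionality is 3732 components; on small runs the rank
  is clamped to `min(n_train - 1, d)` with a warning. PCA is fitted on the
  handcrafted block only, since the learned 256-component stream is
  reported separately in the reference workflow.

### Drop-Weights head and training

The hybrid vector feeds fully connected ReLU layers whose *weights* are
masked by independent Bernoulli draws (rate 0.3 by default), rescaled by
`1/(1 - rate)` so the masked layer is mean-preserving. The masks stay
active at inference: repeated stochastic forward passes approximate draws
from the Bayesian posterior predictive distribution.

Training minimises mean per-label binary cross-entropy — deliberately
without class weighting — using the adaptive-moment optimiser with the
maximum-of-past-variance correction (AMSGrad), He-uniform initialisation,
and an L2 weight penalty. A fresh Drop-Weights mask is sampled per
minibatch. After each epoch the mean per-label accuracy at threshold 0.5 is
computed on the validation split with the deterministic (expected) network,
and the best-on-validation weights are kept. The output-layer bias starts
at the training-prevalence logit so early epochs refine features rather
than base rates. All gradients are computed by the package's own
backpropagation; a finite-difference check in the test suite pins every
layer to ~1e-9 relative error.

Reference-scale hyperparameters (learning rate 1e-6, minibatch 32, 250
epochs, weight decay 0.2) are the `hbnet_config()` defaults. The desk
profile — `hbnet_profile("desk")` — is sized for one CPU: 64 px input,
64-d CNN feature, two 64-wide hidden layers, learning rate 3e-4, minibatch
16, 60 epochs. These values were chosen for stable optimisation of the
small network (the reference learning rate is matched to a far larger
model and dataset); with the 0.3 Drop-Weights rate, smaller batches and a
moderate learning rate are what let the stochastic head converge.

## Uncertainty and the DHC score

For one label, `T` stochastic passes give probabilities `p_1..p_T` with
predictive mean `mu`. The package reports, per (image, label):

* plug-in predictive entropy `H(mu)` in bits (so the binary entropy is
  already on a 0..1 scale — this realises the "normalised uncertainty"
  reporting convention for the denominator);
* the jackknife bias-corrected entropy
  `H_J = T H(mu) - (T-1) mean_i H(mu_{-i})`, which removes the leading
  downward bias of the plug-in estimate at finite `T`. Note that for
  constant samples `H_J` reduces to `H(mu)` — the correction vanishes, it
  does not zero the entropy — and `H_J` can slightly overshoot negative
  near degenerate means, hence the floor below;
* mutual information `H(mu) - mean_t H(p_t)` (the BALD decomposition);
* CPPD, the class predictive probability distance. Each sigmoid label is a
  Bernoulli with outcome probabilities `mu` and `1 - mu`, so the
  best-versus-next-best gap is `|2 mu - 1|`. (An across-labels reading —
  the gap between the two largest per-label means of an image — is
  available as `cppd_mode = "across_labels"`, but per-label is the default
  because the DHC score is defined per label.)
* the DHC score `CPPD / max(H_J, 1e-10)`, capped at 1e6 so tables stay
  finite. The floor matches the magnitude of the smallest published
  per-cell-type cutoffs (1e-10); the cap only exists for finite reporting
  and sorts as top confidence. DHC near 0 marks indifferent, uncertain
  predictions; large DHC marks confident ones.

For reporting, raw scores are min-max normalised to 0..1 per label within
the scored batch (an all-equal batch maps to 1). The raw score is always
co-reported, since min-max normalisation is batch-dependent.

A subtlety worth recording: the mean DHC score *decreases* with MC-sample
dispersion only at a fixed *realised* sample mean. If instead the expected
mean is fixed and the realised mean fluctuates, convexity of
`|2mu - 1| / H(mu)` in `mu` dominates the jackknife term and the trend can
reverse. The package's tests therefore condition on the realised mean when
they assert the dispersion monotonicity.

## Thresholds, metrics and triage

Binary calls use per-label probability thresholds chosen by grid search
(0.01..0.99, step 0.01) maximising the Matthews correlation coefficient on
the validation split; MCC handles the strong class imbalance (Leydig
positive in two-thirds of images, peritubular in one tenth). Performance is
summarised by Hamming loss, macro and micro F1, the exact-match ratio and
mean average precision (all-point AP, modern convention), with per-label
confusion counts; AUC aggregation is deliberately absent (it is not
well-defined for the multilabel task as a whole).

Triage then sorts each label's predictions by normalised DHC and picks the
smallest cutoff whose retained accuracy on the validation split reaches a
target (default 0.99 — matching the retained-accuracy regime the published
cutoffs operate in) while keeping at least half of the records. The cutoff
search formalises what is otherwise read off a confidence map: the spread
of misclassifications along the DHC axis. Cutoffs found on validation are
applied to the test set; `accuracy_discard_curve()` exposes the full
trade-off. The published per-cell-type cutoffs ship as the
`hpa_testis_v1` preset. Whether cutoffs should come from validation or
test data is not pinned down in the reference description; validation is
the default here because using test data would leak the quantity being
estimated.

## Cross-validation

`multilabel_stratified_split()` implements iterative stratification for
repeated k-fold plans: examples carrying the currently rarest label are
placed first, each into the eligible fold with the largest remaining quota
for that label (ties: quota summed over the example's other labels, then
fold occupancy, then the seeded generator), with fold sizes constrained to
differ by at most one. When a grouping column (antibody id) is supplied,
whole groups are assigned so the 1–3 images of one antibody never straddle
folds; grouping is the safe default for antibody-coherent batches, though
whether the original folds respected it is not documented.

## The synthetic generator

Real HPA testis images cannot ship with the package, so
`generate_images()` draws the geometry a scorer actually uses: 1–2
circular tubule cross-sections per 64 px image with concentric germ-cell
rings (outer to inner: spermatogonia, preleptotene, pachytene, round/early,
elongated/late), radial Sertoli wisps, interstitial Leydig blobs seeded in
the tissue between tubules, and a thin peritubular rim. Label-positive
compartments are painted toward DAB brown (110, 70, 40) with a mixing
weight of 0.35 / 0.70 / 1.00 for weak / moderate / strong intensity;
everything else keeps the hematoxylin counterstain (130, 140, 200) —
distinctly lighter than the DAB precipitate, as in real sections — plus
Gaussian noise (sd 8). Weak staining deliberately sits close to the
counterstain: that is where human observers disagree too, and it gives the
trained model a natural error mode for the triage machinery to find.

Labels are drawn from a Gaussian copula whose marginals follow the real
collection qualitatively (Leydig 0.66 most frequent, peritubular 0.10
rarest) with within-cluster latent correlation 0.6 for the premeiotic,
meiotic/postmeiotic and somatic clusters. A colour-rule oracle (mean R - B
over the compartment mask) recovers the generated labels with >= 99%
accuracy, guaranteeing the task is learnable from the images.

What the generator does **not** emulate: nuclear texture, cell-boundary
morphology, staining artifacts, sectioning damage, or inter-laboratory
colour variation. Passing tests on synthetic data therefore demonstrate
that the pipeline's statistics behave as designed — not that the small
network would reach any particular accuracy on real HPA images.

`generate_mc_samples()` complements this with model-free Monte-Carlo
prediction sets of controlled calibration: each item draws a latent
per-label mean from a Beta centred between its true label and 0.5
(position and spread set by a difficulty in [0, 1]), then `T` Beta
samples around that mean. Errors thus arise exactly where predictions are
indifferent, which is the regime in which DHC triage is informative.

## Problem sizes and numerical choices

The package's own end-to-end study (`run_synthetic_study()`, also behind
`scripts/acceptance.R`) uses 600 images split 400/100/100, the desk
profile, and T = 100 MC passes — sizes chosen so the whole study runs in a
few minutes on one CPU while leaving each stage statistically meaningful.
Other conventions: probabilities are clipped at 1e-12 inside the
cross-entropy; leave-one-out means are clipped to [0, 1] against rounding;
the Haralick correlation of a zero-variance image is 0; Hu moments use a
signed log10 transform with 0 mapping to 0; ties in MCC grid search break
toward the lower threshold, ties in DHC ranking toward the
lexicographically smaller image id; all randomness fans out from one
master seed and runs are bitwise reproducible single-threaded.

## Known limitations

* The `vgg19_like` backbone is provided for structural fidelity but is not
  desk-trainable; the uncertainty machinery is backbone-agnostic.
* Handcrafted features are computed once per image (they are
  deterministic), not per MC pass.
* No aleatoric/heteroscedastic decomposition and no post-hoc calibration
  (e.g. temperature scaling) — uncertainty is epistemic-only, as in the
  reference method.
* Min-max DHC normalisation depends on the scored batch; scores from
  different batches are comparable only through the raw ratio.

## A worked example

```{r example}
library(ihctriage)

study <- run_synthetic_study(seed = 1)
glance(study) # metric suite + triage summary
tidy(study) # per cell type
plot_confidence_map(study$records_test, cutoffs = study$cutoffs)
plot_accuracy_discard(study$records_test)
```
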