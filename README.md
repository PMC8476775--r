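# ihctriage

Confidence-aware multilabel classification and triage of immunohistochemistry
(IHC) images.

## The problem

IHC stains a protein of interest brown (DAB) over a blue hematoxylin
counterstain. In human testis, eight cell types are scored per image — five
germ-cell stages arranged as concentric layers of the seminiferous tubule
(spermatogonia, preleptotene, pachytene and round/early, elongated/late
spermatids) plus Sertoli, Leydig and peritubular cells — and a protein may be
expressed in any subset of them, at graded intensity and in different
subcellular compartments. Automating this annotation is only useful if every
prediction carries a confidence that says *when the model should be trusted*:
confident predictions can be accepted automatically, the rest routed to a
human scorer.

`ihctriage` is for image-analysis and proteome-annotation groups who want
that full workflow in R: model, uncertainty, metrics and triage.

## The method

**HBNet.** A hybrid Bayesian neural network combines learned convolutional
features with handcrafted descriptors — HOG (8 orientation bins, 8 px cells,
8×8-cell blocks), the 13 Haralick co-occurrence statistics, and the 7 Hu
moments, z-scored and reduced by PCA — feeding fully connected layers whose
weights are masked by Bernoulli **Drop-Weights** (rate 0.3), active during
both training and inference, with one sigmoid output per cell type. Training
minimises mean binary cross-entropy with AMSGrad; per-label probability
thresholds are chosen by MCC grid search on a validation split.

**Uncertainty.** T stochastic forward passes approximate posterior draws.
For each label with predictive mean μ the package reports the predictive
entropy H(μ) (bits), its jackknife bias-corrected version

    Ĥ_J = T·H(μ̂) − (T−1)·mean_i H(μ̂₍₋ᵢ₎),

the mutual information, the class predictive probability distance
CPPD = |2μ̂ − 1|, and the **DHC confidence score**

    DHC = CPPD / Ĥ_J,

min-max normalised per label for reporting. DHC → 0 marks uncertain
predictions; large DHC marks confident ones. Ranking predictions by DHC and
cutting at a per-label threshold chosen on validation data splits the test
set into auto-labelled and manual-review subsets, trading a bounded discard
fraction for a large accuracy gain on what is retained.

Everything is testable offline: a synthetic generator draws tubule-geometry
IHC images (concentric germ-cell rings, Sertoli wisps, Leydig blobs,
peritubular rim; DAB-brown staining scaled by intensity over a lighter blue
counterstain) with correlated multilabel ground truth, plus calibrated
synthetic Monte-Carlo prediction sets.

## A worked example

```r
library(ihctriage)

study <- run_synthetic_study(seed = 1) # ~10 min on one CPU
glance(study)
```

```
#> # A tibble: 1 × 10
#>       n hamming_loss macro_f1 micro_f1 exact_match mean_average_precision
#>   <int>        <dbl>    <dbl>    <dbl>       <dbl>                  <dbl>
#> 1   100        0.186    0.751    0.770        0.22                  0.811
#> # mean_overall_accuracy 0.814, mean_retained_accuracy 0.947,
#> # mean_discard_fraction 0.45, chance_exact_match 0.0110
```

Reading this: on 100 held-out synthetic images the network gets 81.4% of the
individual cell-type calls right (Hamming loss 0.186) and 22% of images fully
right across all eight labels — twenty times the 1.1% chance level of
guessing at label prevalence. Triaging by DHC with cutoffs chosen on the
validation split discards on average 45% of predictions per cell type and
lifts the accuracy of what remains to 94.7% — the accuracy-vs-workload
trade-off the score exists for.

```r
tidy(study) # per-cell-type confusion counts, cutoffs, discard fractions
plot_confidence_map(study$records_test, cutoffs = study$cutoffs)
plot_accuracy_discard(study$records_test)
```

For real images: `read_annotation_table()` + `load_image()` /
`resize_image()` bring in data, `reduce_handcrafted()` + `build_hbnet()` +
`hbnet_train()` fit the model, `mc_predict_many()` + `uncertainty_records()`
score it, `grid_search_thresholds()`, `select_cutoffs()` and
`apply_cutoffs()` complete the triage. A thin CLI (`exec/ihctriage`) chains
the same functions as subcommands
(`simulate | extract-features | train | predict | score | evaluate | triage | crossval | study`).

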