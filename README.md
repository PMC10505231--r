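# milfc — weakly-supervised chromosome-arm fold-change estimation from whole-slide images

`milfc` is an R toolkit for predicting the copy-number **fold change (FC)**
of chromosome arms 1p and 19q from H&E whole-slide images, and for turning
the two estimates into an astrocytoma / oligodendroglioma call. Among
IDH-mutant diffuse gliomas, combined loss of one copy of 1p and 19q
("1p/19q codeletion") is diagnostic of oligodendroglioma; an arm's FC is
1.0 in normal tissue and falls to `1 − 0.5·t` (≈ 0.5–0.8) when one allele
is lost at tumor purity `t`. The package is aimed at computational
pathology researchers who want a tested, fully deterministic, CPU-only
reference implementation of this pipeline — and at anyone who needs its
building blocks: slide tiling and filtering, min-max multiple-instance
aggregation, bootstrap ROC evaluation.

Training needs only a slide-level label per arm (weak supervision — no
patch annotations). Each slide is a bag of 224×224 patches embedded by a
frozen feature extractor; per arm, a linear scorer assigns each patch a raw
score `s_i = w·f_i + b`, the `N` highest and `N` lowest scores are
selected (CHOWDER-style min-max aggregation, default `N = 100`), and a
three-layer MLP (200–100–1, sigmoid after every layer) maps them to a
slide FC estimate in (0, 1):

```
fc_hat = σ(W3 σ(W2 σ(W1 [top_N(s); bottom_N(s)] + b1) + b2) + b3)
```

Estimators are trained with Adam (lr 1e-4, weight decay 5e-4, dropout 0.5
on the MLP's first two layer inputs) against the mean squared error to
NGS-derived FC labels. A logistic model fuses the two arms,
`P(oligo) = σ(β0 + β1·fc_1p + β2·fc_19q)`, trained by binary
cross-entropy; both fitted coefficients are negative (lower FC ⇒ more
deletion ⇒ oligodendroglioma). Patch scores become interpretable heatmaps
(red = loss, blue = intact, purple = omitted background/blood patches)
plus tables of the 100 highest/lowest-scoring representative patches.

Also included:

* the two clinical labeling rules — the NGS rule (oligodendroglioma iff
  both mean arm FCs < 0.8) and the FISH rule (deletion iff the single-
  target signal ratio exceeds 50% over more than 60 evaluable nuclei);
* the evaluation harness: R² per arm, Mann-Whitney AUC, Youden-J cutoffs
  with confusion metrics, 1000-replicate stratified bootstrap 95% CIs, and
  repeated stratified 60/20/20 split protocol;
* a synthetic-slide generator (feature bags with planted, purity-scaled
  deletion signal and image fixtures for the filters) so the entire
  pipeline is testable without any clinical data.

## Worked example

Simulate a 120-slide cohort (balanced tumor types, purities uniform on
\[0.4, 1\], planted 2-SD deletion signal), then run the repeated-split
protocol: per split it trains both arm estimators, fits the fusion on the
training split, and evaluates on the held-out test split.

```r
library(milfc)

co <- simulate_cohort(120, n_patches_range = c(100L, 250L), feature_dim = 48L,
                      effect_size = 2, label_noise_sd = 0.02, seed = 1)
co
#> <slide_cohort> 120 slides (60 oligodendroglioma, 60 astrocytoma)

cfg <- train_config(n_extreme = 15L, max_epochs = 100L,
                    early_stop_patience = 40L, seed = 1L)
report <- run_protocol(co, n_splits = 2, config = cfg, n_boot = 500, seed = 1)
report
#> <eval_report> 2 splits, 500 bootstraps, 95% CI
#>   mean R2: 1p 0.827, 19q 0.829 | AUC: 1p 1.000, 19q 1.000, fused 1.000 (CI 1.000-1.000)
#>   accuracy 1.000, precision 1.000, recall 1.000, F1 1.000 at mean cutoff 0.500
```

Reading the numbers: the held-out R² ≈ 0.83 per arm says the estimators
recover not just deletion status but the purity-scaled FC value; the
fused AUC of 1.000 (bootstrap CI 1.000–1.000) says the two-arm logistic
separates the simulated tumor types perfectly at these settings; and the
confusion metrics are computed at the Youden-J cutoff on each test split.
`tidy(report)` returns the per-split rows plus the across-split average,
`glance(report)` the one-row summary (which also carries the planted-patch
localization AUCs, here 0.80/0.79), and `autoplot(report)` draws the
fused ROC curves.

The label-derivation rules work on plain tables:

```r
genes <- tibble::tibble(gene = c("TP73", "MEGF6", "CRX", "ZNF44"),
                        arm = c("1p", "1p", "19q", "19q"),
                        log2_fc = log2(c(0.58, 0.66, 0.61, 0.63)))
ngs_classify(mean_arm_fc(genes, "1p"), mean_arm_fc(genes, "19q"))
#>          tumor_type borderline
#> 1 oligodendroglioma      FALSE

fish_deletion_call(72, 41)
#>      call signal_ratio
#> 1 deleted    0.5694444
```

For image-level preprocessing, `tile_slide()`, `filter_patches()` (Canny
edge count < 23 ⇒ background; HSV bounds ⇒ blood), `normalize_color()`
(Reinhard-style CIELAB statistics matching for external cohorts) and
`extract_features()` take a slide from pixels to a cached feature bag; a
thin command-line wrapper `exec/milfc` exposes the stages
(`simulate | prep | extract | train | predict | fuse | heatmap |
evaluate | run`) for shell use, and `run_pipeline()` orchestrates the
whole thing with content-hash stage caching and byte-identical re-runs.

See `vignettes/milfc-methods.Rmd` for the model, its assumptions, every
tunable parameter, and the design decisions.

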