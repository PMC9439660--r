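# histoscore

Histology tile classification and prognostic scoring for whole-slide
images, at desk scale.

## The problem

In resected early-stage hepatocellular carcinoma (HCC), recurrence risk is
written into the slide itself: the balance of tumor, normal liver, portal
tracts, fibrosis, necrosis and lymphocyte infiltrates, and the texture of
each. A now-standard computational-pathology recipe turns an H&E
whole-slide image into a prognostic score:

1. **mask** tissue against the white slide background (Otsu threshold on
   the blurred saturation channel);
2. **tile** the slide into fixed squares and **standardize staining** with
   a Reinhard-style colour transfer in the decorrelated log colour space
   lαβ, computed over tissue pixels only;
3. **classify** each tile into six tissue categories — tumor region (TR),
   normal liver tissue (NLT), portal area (PA), fibrosis (FI),
   hemorrhage/necrotic area (HNA), lymphocyte area (LA) — and smooth the
   resulting label map morphologically;
4. **extract signatures** per slide: class area proportions plus colour,
   GLCM texture and nuclei-proxy morphometry averaged over each class's
   top-K most confident tiles;
5. **score**: a LASSO-penalized Cox model selects signatures and the
   histological score is the linear combination HS = Σⱼ βⱼ xⱼ; a maximally
   selected log-rank cutpoint splits the cohort into high/low risk
   (high iff HS > cutoff);
6. **evaluate** discrimination: Harrell's C-index, time-dependent ROC
   with censoring weights, calibration, continuous net reclassification
   improvement (NRI), Kaplan–Meier/log-rank, and Cox hazard ratios.

`histoscore` implements the full chain as a tested R package. Because
clinical WSIs cannot ship in a package, it includes a first-class
synthetic generator: six parametric H&E-like textures with per-pixel
ground truth, and a survival cohort whose log-hazard is a known sparse
linear function β'x of the slide signatures (Weibull baseline, tuned
uniform censoring). Every stage is validated against closed-form oracles
or the generator's planted truth. See `vignettes/histoscore-methods.Rmd`
for the modelling details and design decisions.

## Worked example

```r
library(histoscore)

# a synthetic slide and its tissue mask
slide <- compose_slide(c(0.45, 0.25, 0.08, 0.12, 0.05, 0.05),
                       size = 480, seed = 7, n_cells = 8)
mask <- tissue_mask(slide$image)
#> tissue fraction: 0.84 (Otsu threshold 0.166)

# train the six-class tile classifier on rendered tiles
batch <- synth_tile_batch(60, side = 96, seed = 1)
sp    <- split_dataset(batch, seed = 1)
model <- train_classifier(sp$train, sp$val, classifier_config(seed = 1))
evaluate(model, sp$test)
#> tile test accuracy: 1.000; tumor PR-AUC: 1.000

# classification map -> top-K tiles -> slide signature
map  <- smooth_map(build_map(slide$image, mask, model))
topk <- top_k_tiles(map, k = 5)
sig  <- slide_signature(map, topk,
          function(r, c) slide$image[r * 96 + 1:96, c * 96 + 1:96, , drop = FALSE])
sig$values[paste0("prop_", hcc_classes())]
#>  prop_TR prop_NLT  prop_PA  prop_FI prop_HNA  prop_LA
#>     0.72     0.12     0.08     0.00     0.08     0.00
# (a 480 px slide has only a 5x5 tile grid, so mixed border tiles coarsen
#  the proportions toward the dominant class)

# survival cohort with a planted sparse log-hazard, LASSO-Cox score
cohort <- default_cohort(600, seed = 7)
X   <- attr(cohort, "signatures")
fit <- fit_lasso_cox(X, cohort$time, cohort$event, seed = 7)
hs  <- compute_score(fit, X)
cut <- optimal_cutoff(hs, cohort$time, cohort$event)
#> selected 38 features; C-index 0.888; cutoff -20.795; log-rank p 4.1e-147
#> 1-year AUC 0.966; high-risk n=185, low-risk n=415
```

The C-index of 0.888 sits at the oracle level of the generator (the true
linear predictor's concordance is calibrated to ≈ 0.88), showing that
LASSO-Cox recovers the planted signal; the log-rank p confirms the
cutpoint separates the risk groups.

A full demo pipeline — slides → classifier → maps → signatures → cohort →
score → report, with a checksummed manifest — runs with:

```r
run_end_to_end(run_config(out_dir = "demo_run", seed = 1))
```

or from a shell via `exec/histoscore.R demo --out demo_run --seed 1`.

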