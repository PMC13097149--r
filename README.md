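# lesionnet

Desk-scale, fully native R implementation of a morphology-guided,
explainable, uncertainty-aware skin-lesion classification pipeline for
dermoscopy-style images.

**Who it is for.** Researchers and students who want to study — on a single
CPU, with no deep-learning framework and no external dataset — how the
pieces of a safe lesion-classification system interact: lesion segmentation
that guides the classifier, attention that is *regularized to sit on the
lesion*, explanation maps aligned with lesion morphology, and Monte Carlo
dropout uncertainty that drives selective prediction (triage).

## The model

Six stages, trained in two phases (segmenter first, then classifier):

1. normalize: `x' = (x - mu) / sigma` (ImageNet channel statistics),
   resized to a working resolution (default 64 x 64);
2. segment: a depth-3 U-Net (~130k parameters) predicts a soft lesion mask
   `M`, trained with soft Dice loss `1 - 2|M∩G| / (|M|+|G|)`;
3. suppress background: `x_m = x' ⊙ M` (optional attenuation keeps faint
   context);
4. classify: a small bias-free CNN backbone with squeeze-excite channel
   attention `A_c` and convolutional spatial attention `A_s`;
   `f_a = f ⊙ A_c ⊙ A_s`, then GAP → projection → dropout → softmax;
5. explain: Grad-CAM on `f_a`, aligned with the mask
   (`M_final = M_exp ⊙ M`), plus pixel saliency; the scalar
   `explanation_coverage` measures the in-mask fraction of attribution mass;
6. quantify uncertainty: MC dropout (`T` stochastic passes, population
   moments `mu`, `sigma^2`), rejection analysis at threshold `theta_u`,
   reliability bins, ECE and Brier score.

The composite objective is
`L = lambda1*L_seg + lambda2*L_cls + lambda3*L_att + lambda4*L_unc`, where
`L_att = 1 - sum(A ⊙ M)/sum(A)` pulls spatial attention into the lesion and
`L_unc` is a shifted confidence penalty `log(C) - H(p)`.

A seeded synthetic generator stands in for real dermoscopy: radially
perturbed elliptical lesions with controllable asymmetry, border
irregularity and pigment heterogeneity over a skin-tone background, with
hair strokes, illumination gradient and noise added after the ground-truth
mask is captured. See the methods vignette
(`vignettes/lesionnet-methods.Rmd`) for every design decision.

## Worked example

```r
library(lesionnet)

cfg <- experiment_config(n_per_class = 200L, k = 2L, seed = 42L)
res <- run_experiment(cfg, out_dir = "run")
str(res$summary)
```

Output of that exact run (about 6 minutes on one CPU):

```
List of 9
 $ accuracy         : num 0.987
 $ precision        : num 0.987
 $ recall           : num 0.987
 $ f1               : num 0.987
 $ macro_auc        : num 0.999
 $ mean_val_dice    : num 0.975
 $ per_fold_accuracy: num [1:2] 0.98 0.993
 $ n_folds_ok       : int 2
 $ n_folds_failed   : int 0
```

`accuracy` is the fold-mean validation accuracy of the 3-class synthetic
task; `mean_val_dice` the segmenter's held-out Dice overlap. The run
directory contains, per fold: training histories, a predictions table
(label, prediction, confidence, uncertainty), the rejection curve, the
calibration report (fold-1 ECE 0.279, Brier 0.248 — MC smoothing makes the
mean prediction underconfident), Grad-CAM overlay PNGs and an explanation
coverage table. Pooled over folds, misclassified samples carry roughly
twice the mean uncertainty of correct ones (0.0125 vs 0.0064; ranking
AUROC 0.81), and the selected rejection threshold `theta_u = 0.0187`
rejects 2% of samples while removing none of the correct predictions
(accepted accuracy 98.0%).

Single-image use:

```r
s   <- generate_sample(synthetic_class_specs()[[2]], 64, seed = 7)
mdl <- res$folds[[1]]$classifier
p   <- predict_lesion(mdl, s$image)        # class probabilities + mask
em  <- align_explanation(grad_cam(mdl, s$image))
mp  <- mc_predict(mdl, s$image, T = 25, seed = 1)
uncertainty_score(mp)                      # variance of the predicted class
```

## Command line

```sh
Rscript inst/cli/lesionnet.R generate --out data --n-per-class 50 --seed 1
Rscript inst/cli/lesionnet.R train-seg --data data --out seg.rds --seed 1
Rscript inst/cli/lesionnet.R train-cls --data data --segmenter seg.rds --out cls.rds
Rscript inst/cli/lesionnet.R predict --model cls.rds --image data/images/s0001_c0.png
Rscript inst/cli/lesionnet.R run --out run --seed 42
Rscript inst/cli/lesionnet.R compare run_full run_ablation --out ablation.csv
```

Subcommands: `generate`, `train-seg`, `train-cls`, `predict`, `explain`,
`uncertainty`, `evaluate`, `run`, `compare`.

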