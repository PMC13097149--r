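---
title: "Morphology-guided, explainable, uncertainty-aware lesion classification: methods"
author: "lesionnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lesionnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Dermoscopic skin-lesion classifiers are usually evaluated on accuracy alone,
yet clinical deployment needs three further properties: the model should
attend to the lesion rather than to background artifacts (hair, shadows,
rulers), it should explain which regions drove a prediction, and it should
know when it does not know, so that ambiguous cases can be deferred to a
dermatologist. `lesionnet` implements a desk-scale version of a pipeline
that addresses all three at once, in six stages:

1. **Normalization** — the input image $x$ is resized to a fixed working
   resolution and normalized channel-wise, $x' = (x - \mu)/\sigma$, with the
   conventional ImageNet constants $\mu = (0.485, 0.456, 0.406)$,
   $\sigma = (0.229, 0.224, 0.225)$.
2. **Lesion localization** — a small U-Net (depth 3, base width 16, about
   130k parameters) predicts a soft lesion mask $M = U(x') \in [0,1]^{H
   \times W}$, trained with soft Dice loss
   $L_{seg} = 1 - (2\sum MG + \varepsilon)/(\sum M + \sum G + \varepsilon)$
   against the ground-truth mask $G$.
3. **Background suppression** — the classifier sees
   $x_m = x' \odot (M + a(1 - M))$. With attenuation $a = 0$ (the default)
   this is the plain masked product; a small $a$ retains faint context.
4. **Attention classification** — a compact convolutional backbone extracts
   features $f$; a squeeze-excite channel gate $A_c$ and a channel-pooled
   convolutional spatial gate $A_s$ (both sigmoid-bounded) refine them as
   $f_a = f \odot A_c \odot A_s$; global average pooling, a projection
   layer with dropout and a linear softmax head produce class probabilities.
5. **Explanation** — Grad-CAM on $f_a$ gives $M_{exp}$, aligned with the
   predicted mask as $M_{final} = M_{exp} \odot M$; pixel saliency
   (max-channel absolute input gradient) complements it. The scalar
   `explanation_coverage` = in-mask fraction of attribution mass quantifies
   whether explanations stay on the lesion.
6. **Uncertainty** — Monte Carlo dropout at inference gives $T$ probability
   vectors $p_t$ with population moments $\mu = \frac1T \sum p_t$,
   $\sigma^2 = \frac1T \sum (p_t - \mu)^2$; a scalar uncertainty drives
   selective prediction (reject when score $> \theta_u$), with the
   threshold chosen on validation data and reliability assessed by ECE and
   the Brier score.

The composite training objective is
$L_{total} = \lambda_1 L_{seg} + \lambda_2 L_{cls} + \lambda_3 L_{att} +
\lambda_4 L_{unc}$ with the attention-alignment regularizer
$L_{att} = 1 - \sum (A \odot M) / \sum A$, where $A$ is the spatial
attention map bilinearly upsampled to mask resolution. $L_{att}$ is the
core morphology-guidance mechanism: it is scale-free in $A$ and
differentiable, and pushes attention mass into the predicted lesion.

## Design choices where the design was open

- **Attention internals.** The source method names only "spatial and
  channel attention modules". We use the conventional reading: a
  squeeze-excite bottleneck for channels and a mean/max channel-pooled
  3x3 convolution for space, both sigmoid-gated, applied multiplicatively
  to $f$ (the literal $f_s \odot f_c$ is dimensionally ambiguous).
- **Which map is regularized.** $A$ in $L_{att}$ is the spatial attention
  map, not a Grad-CAM map: the loss must be cheaply differentiable at every
  training step.
- **The calibration loss.** No formula exists for $L_{unc}$ in the source.
  The default here is a shifted confidence penalty $\log C - H(p)$
  (nonnegative, zero at the uniform prediction, same gradient as the
  classical $-H(p)$ penalty); it can be switched off. This is an explicit
  assumption, recorded in logs.
- **Loss weights.** $\lambda = (1, 1, 0.5, 0.01)$ by default, exposed in
  config and logged with every run. The natural first guess for the
  calibration weight, $\lambda_4 = 0.1$, measurably *mis*calibrates the
  desk-scale models — it drags predictions toward uniform (mean confidence
  0.57 at 96% accuracy, ECE 0.39) and erases the uncertainty ranking
  (error-detection AUROC 0.45–0.62). At $\lambda_4 = 0.01$ the same fold
  gives ECE 0.04 and AUROC above 0.9.
- **Bias-free backbone.** The classifier's convolutions carry no bias
  term, as in batch-norm backbones where biases fold into normalization.
  Consequence: a masked-to-zero background produces exactly zero features,
  so attribution maps cannot acquire a constant background plateau.
- **Stability.** The ratio-form alignment loss has an unbounded gradient
  as $\sum A \to 0$; without countermeasures one cross-validation fold
  collapsed to uniform predictions (attention gates saturated shut). Three
  standard remedies are built in: global gradient-norm clipping (default
  5 per sample), a clamped denominator in the alignment gradient, and
  attention gate biases initialized at $+1$ so the gates start open
  (near-identity), as squeeze-excite practice recommends.
- **Where dropout lives.** A feature-space dropout layer (p = 0.1) sits in
  the mid-backbone in addition to the head dropout (p = 0.25). Head-only
  dropout yields almost no epistemic signal: it perturbs a single pooled
  embedding. Feature-space dropout, trained in and kept active for MC
  sampling, makes the predictive variance respond to how fragile the
  feature evidence is.
- **Staged, not joint.** The segmenter is trained first and frozen during
  classifier training. The staged reading matches the described pipeline
  order, lets masks be precomputed (a large speedup), and keeps the
  ablation "without segmentation" exact. A joint fine-tuning phase was
  considered and dropped: at desk scale it adds optimization coupling
  without measurable benefit on the synthetic tasks.
- **Soft vs binarized mask in the product.** $x_m$ uses the soft $M$ as
  written; binarization is available for figures and overlays.
- **Uncertainty scalar.** The per-class variance vector is reduced to the
  variance of the predicted class by default (entropy of the predictive
  mean as the alternative). Rejection uses strict `score > theta`.
- **MC sampling shortcut.** Everything before the first stochastic layer
  (the backbone dropout) is deterministic, so `mc_predict` evaluates that
  trunk once per image and re-samples only the stochastic tail $T$ times —
  the same distribution as $T$ full passes, several times faster.

## The synthetic world

No public dermoscopy dataset ships lesion masks alongside the 7-class
labels the source method was trained on, and GPU-scale training is out of
scope, so the package carries a seeded generator that emulates the
morphological axes dermatologists actually use (the ABCD mnemonic):
**A**symmetry (ellipse squashing plus a one-sided radial bulge),
**B**order irregularity (unit-norm random radial harmonics scaled by an
amplitude parameter), **C**olour (palette patches blended with a
heterogeneity weight), and **D**iameter (radius as a fraction of the image
side). Hair strokes (quadratic Bezier curves with Gaussian falloff), a
linear illumination ramp and sensor noise are overlaid *after* the mask is
captured, so the ground truth marks exactly the lesion support.

The default three classes are chosen so that colour alone cannot solve the
task: classes 0 and 1 share the same brown palette and size and differ in
border irregularity (0.05 vs 0.4), asymmetry (0.08 vs 0.5) and
heterogeneity (0.15 vs 0.7); class 2 is a smaller reddish vascular-like
lesion. Border irregularity is measurably recoverable: the coefficient of
variation of the centroid-to-boundary radius separates the two brown
classes with at least 95% accuracy over 100 samples.

What the generator does **not** emulate: real dermoscopic texture
(pigment networks, dots/globules), camera vignetting, colour calibration
differences between clinics, class imbalance, and genuinely ambiguous
histopathology. A green end-to-end test therefore establishes that the
pipeline's machinery works and that its couplings (masking, alignment,
uncertainty) behave as designed — not that it would reach any particular
accuracy on HAM10000-like data.

## Numerical choices

- Dice smoothing $\varepsilon = 10^{-6}$; two empty masks score 0 (treated
  as perfect agreement).
- Cross-entropy probabilities floored at $10^{-12}$.
- Degenerate all-zero attention maps: $L_{att}$ returns 0 with a warning;
  `explanation_coverage` refuses zero-mass maps with an error.
- Mask binarization breaks ties toward foreground (`>= t`).
- Explanation maps are max-normalized (not min-max) so zero stays zero.
- Argmax predictions break ties toward the lowest class index.
- Bilinear resampling uses the half-pixel-centre convention; its backward
  pass is the exact adjoint (verified by an inner-product identity).
- AdamW with decoupled weight decay $10^{-4}$ and cosine-annealed learning
  rate; gradients are averaged over the mini-batch.
- All randomness flows through R's RNG via seeded scopes; per-sample seeds
  are a deterministic hash of (master seed, index), so datasets can grow
  without reshuffling earlier samples. In single-threaded BLAS mode a rerun
  of a full experiment reproduces metrics files bit-identically.

## Training profiles

The full-scale protocol (AdamW, learning rate $10^{-4}$, cosine annealing,
batch 16, early stopping patience 25, max 150 epochs) describes fine-tuning
large ImageNet-pretrained backbones; it is reachable through
`cls_config()`. The desk-scale defaults train small nets from scratch at
64x64 and use a raised learning rate (2e-3) and short schedules
(segmenter 6-12 epochs, classifier 15-20 epochs, patience 5), which the
synthetic tasks comfortably converge under.

## Two measured negative results

Both are asserted (and in the first case fail honestly) in the test suite;
neither was papered over by changing the generator or thresholds.

**Lesion-free inputs do not look "uncertain" to MC dropout.** With the
literal masked product, a lesion-free image is suppressed to (near-)zero
input; the bias-free backbone then produces near-zero features, the output
is an almost constant function of the head biases, and the MC variance is
*lower* than on in-distribution images (measured $8\times10^{-5}$ vs
$6.5\times10^{-3}$), not higher. Background attenuation and feature-space
dropout do not change the sign. Error detection *within* the distribution
works well (misclassified samples carry roughly double the mean
uncertainty; ranking AUROC 0.81) — but detecting "there is nothing here to
classify" is structurally beyond output-space MC variance in this
architecture. A deployment would flag empty predicted masks instead; that
rule is deliberately not folded into `uncertainty_score`, which implements
the stated mechanism.

**Raw Grad-CAM can explain a class by its absence.** In the synthetic
world the smooth-bordered class is recognized largely by the *lack* of
irregularity features, so its raw Grad-CAM places positive evidence in the
background ring and near-zero mass inside the lesion (raw in-mask coverage
0.02–0.08). This is the known failure mode of class-activation maps for
absence-coded classes. The pipeline's mask-alignment step is precisely the
prescribed remedy: aligned coverage is 0.95–0.99. The quantitative
morphology-guidance guarantee is therefore asserted on the spatial
attention map (which the alignment loss trains directly) and on the
aligned explanation, not on the raw CAM.

## Known limitations

- The segmenter requires mask supervision; with real datasets the masks
  must come from an external source (the study data itself has none).
- Saliency is computed with respect to the working-resolution normalized
  input, holding the predicted mask fixed.
- Weighted-average metrics skip classes absent from the evaluated labels
  (with a warning); one-vs-rest AUC uses midranks under ties.
- The Brier score degrades to its binary (confidence vs correctness) form
  when full probability vectors are not supplied.
- The rejection-threshold scale depends on the chosen uncertainty scalar;
  thresholds from other implementations are not transferable.

All empirical statements above are computed by the test-suite or by
`run_experiment()`; none are copied from external results.
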