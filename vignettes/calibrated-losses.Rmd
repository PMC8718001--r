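---
title: "Calibration-aware losses, ensembles, and the desk-scale synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration-aware losses, ensembles, and the desk-scale synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calens)
```

## The model family

`calens` is organized around one idea: a classifier can lower its
training loss either by becoming more accurate or by becoming more
confident, and under class imbalance the second route is cheaper and
harmful. The package therefore treats the *batch calibration gap*

$$\mathrm{gap} \;=\; \Bigl|\; \tfrac1N\sum_{i=1}^N c_i \;-\;
  \tfrac1N\sum_{i=1}^N p_{i,\hat k_i} \;\Bigr|$$

— the absolute difference between batch accuracy (mean of the
correctness indicators $c_i$) and batch confidence (mean probability
assigned to the predicted class $\hat k_i = \arg\max_k p_{ik}$) — as a
first-class quantity, and builds losses of the form
$\mathrm{base} + \lambda\cdot\mathrm{gap}$.

Two points about the gap deserve emphasis:

* **It is a batch statistic.** It is computed once per mini-batch, not
  per sample, and is added after the per-sample losses are averaged.
  Its value (and its gradient) therefore depend on the batch size; the
  training engine's default of 32 is part of the loss definition in
  practice, and is stated wherever results are reported.
* **Its gradient contract.** The correctness indicator and the argmax
  that selects the predicted class are piecewise constant; both are held
  fixed during differentiation, so gradients flow only through the
  probability assigned to the predicted class. With this convention
  every loss in the registry has an analytic gradient with respect to
  pre-softmax scores, and the test suite verifies all of them against
  central finite differences (relative error below $10^{-4}$ on random
  batches; observed agreement is near $10^{-10}$).

The registry (`classification_loss_names()`) contains twelve losses:
the four standard ones (cross-entropy, KL divergence, categorical focal
with $\gamma = 1$, categorical Hinge), label-smoothed cross-entropy and
focal ($\sigma = 0.2$; the smoothed-focal variant is simply the focal
loss applied to smoothed targets, as no other construction is
standard), the entropy-regularized cross-entropy
($\mathrm{CCE} - \beta H(p)$ with $\beta = 2$, which penalizes peaked
output distributions and can also be read as an output-activity
regularizer — under the batch-mean reduction the two deployments are
identical), and the calibrated family: calibrated CCE
($\lambda = 10$), calibrated KL ($\lambda = 1$), calibrated focal
($\gamma = \lambda = 1$), calibrated Hinge ($\lambda = 10$) and the
calibrated negative entropy loss ($\beta = 10^{-3}$, $\lambda = 10$).
The calibrated-CCE construction is $\mathrm{CCE} + \lambda\,
\mathrm{gap}$, by analogy with the other calibrated losses; natural
logarithms are used throughout, so values are in nats.

### Segmentation losses

The five binary segmentation losses (BCE, weighted BCE-Dice, binary
focal, Tversky, focal Tversky) use soft counts
$TP = \sum g p$, $FN = \sum g(1-p)$, $FP = \sum (1-g)p$ and a smoothing
constant $s = 1$ in both numerator and denominator of the overlap
ratios, so empty masks never produce $0/0$. Defaults follow the
originating literature where this package's sources are silent:
$\alpha = 0.7$, $\beta = 0.3$ for Tversky, $\gamma_t = 0.75$ for focal
Tversky, $w_{\mathrm{bce}} = 0.5$ for the compound loss, $\gamma_f = 2$
for binary focal, all configurable. One algebraic subtlety: Dice is the
$\alpha = \beta = 0.5$ Tversky loss *exactly* only for the unsmoothed
ratios; the smoothing constant enters the two ratios differently, so
the identity tests in this package set `smooth = 0`, where it holds to
machine precision, and the default `smooth = 1` keeps the standard
field convention for training.

## The synthetic-data module

No external imaging data ships with or is downloaded by this package.
The generators produce:

* **Labels** from arbitrary class probabilities (`gen_labels`), used
  with a 30/50/20 split to emulate the imbalance of a three-class
  pediatric chest-radiograph task.
* **Prediction batches with controlled calibration**
  (`gen_prediction_batch`). Exactly `round(N * accuracy)` rows (a
  seeded random subset) have their argmax on the true label, and argmax
  probabilities are Beta draws with mean `confidence` (concentration
  50, clamped above $1/K$). The exact-count construction — rather than
  per-row Bernoulli draws — is deliberate: the generator's purpose is
  to *control* realized accuracy, and exact counts remove the
  $O(N^{-1/2})$ binomial noise so that the recovered calibration gap
  matches $|a - c|$ to a few thousandths at $N = 2000$ by construction.
* **Model zoos** (`gen_model_zoo`) with per-model accuracies and an
  `agreement` knob: a fraction `agreement` of rows reuse one shared
  random draw across models, so errors and confidences coincide there;
  `agreement = 1` with equal accuracies yields identical models.
  Correctness draws are stratified uniforms, again to keep realized
  accuracies tight.
* **Toy chest images** (`gen_sample`): two elliptical "lungs" (the
  binary mask) over Gaussian background noise (sd 0.05), with
  class-specific structure strictly inside the mask — one bright focal
  blob for class 0 ("bacterial-like"), at least four low-contrast
  streaks over both lungs for class 2 ("viral-like"), nothing for
  class 1 ("normal"). The geometry is jittered per seed but always
  yields exactly two 4-connected mask components. The classes are
  separable even by a linear model on raw pixels (the suite checks
  held-out MCC $> 0.5$ with ridge multinomial regression), and easily
  learnable by the tiny convolutional networks.

What the generator does **not** emulate: radiographic texture, anatomy
beyond two ellipses, label noise, acquisition artifacts, or
inter-observer variability. A passing test suite therefore demonstrates
the correctness of the algorithms and the learnability pipeline, not
clinical performance.

## The tiny training engine and the desk-scale study

The networks are built from a small pure-R layer engine (stride-1
convolutions via patch gathering, 2×2 max pooling, nearest-neighbour
upsampling with skip concatenation, global average pooling, dense
layers) with hand-derived backpropagation, verified end to end against
finite differences. Parameters live in an environment, so a truncated
encoder genuinely shares (and co-mutates) weights with its parent
segmenter — the mechanism behind modality-specific transfer.

The `tiny` backbone (stage widths 8/16/32, leaky-ReLU activations,
~15k parameters for the segmenter, ~24k for a classifier) and the
desk-scale sizes are the package's own choices, stated once here: 32×32
images; 200 training / 50 held-out pairs for segmentation; 300 training
(≈ 90/150/60 per class) / 90 held-out images for classification; Adam
with learning rate $3\times10^{-3}$ and 50 epochs for representation
learning; 12 epochs of BCE for the segmenter. The full-scale protocol
defaults (SGD, learning rate $10^{-3}$, momentum 0.9 for
classification; Adam $10^{-3}$ for segmentation; 10% validation split
with a fixed seed; plateau learning-rate halving with patience 5; best
checkpoint by validation loss) remain the `train_config()` defaults.

### Why the calibrated losses need a two-phase schedule at this scale

Applied from a randomly initialized head, the $\lambda = 10$ penalty
produces a force on the predicted-class score of magnitude
$\lambda\,p(1-p)/N$ per batch — several times the cross-entropy signal
$(1-p)/N$ — whose sign flips with the batch-level comparison of
accuracy and confidence. A network with a few tens of thousands of
parameters has no redundancy against this oscillating, coherent
"flattening" force: in controlled experiments its features collapse to
constants and never recover, even when the run starts from a fully
trained model. At full scale the same losses engage only after a
pretrained backbone is already accurate, so the gap (and hence the
penalty) is small throughout.

`train_study_classifier()` therefore reproduces that regime explicitly:
a *representation phase* (plain cross-entropy, two
validation-loss-selected restarts) followed by a *calibration phase*
that optimizes the full calibrated objective over the output dense
layer — the parameters that carry confidence — with SGD at
$10^{-2}$ for 20 epochs. The result is a model whose held-out MCC
matches the representation phase while the training-batch calibration
gap drops to about 0.01. Losses without the gap penalty (including the
entropy-regularized cross-entropy, whose flattening force is smooth and
deterministic) train end to end in one phase. Model selection in both
phases uses only the validation split.

The model-level ensemble stage: the three classifiers'
deepest convolutional feature maps are concatenated, reduced by a 1×1
convolution (to one constituent's width — the tiny-scale analogue of
the full-scale 1536 → 512 reduction), pooled, and classified by a fresh
softmax layer trained on top of frozen features.

## Numerical conventions

* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before any
  logarithm.
* Majority-vote ties break by highest mean probability across models,
  then lowest class index — deterministic and order-independent.
* Ensemble weights are constrained to the probability simplex
  (non-negative, summing to one — the constraints optimal log-loss
  weights satisfy in practice) and found by projected-gradient descent with Armijo
  backtracking on the convex log-loss objective, with a first-order
  optimality check; the suite verifies agreement with an exhaustive
  0.01-step grid search and that the optimum never exceeds the best
  single model.
* The contrast stretch uses inverse-ECDF (type-1) percentiles, which
  make it exactly idempotent; interpolated percentiles would leave a
  residual of order $1/N$ after re-application on small images.
* Bicubic resampling uses the Catmull-Rom kernel with pixel-center
  alignment and clamped borders; outputs are clipped back to $[0,1]$
  because the kernel can overshoot.
* Augmentation applies the identical affine transform to image
  (bilinear) and mask (nearest-neighbour, re-binarized at 0.5), with
  background fill 0, so no phantom foreground appears.
* Multi-class MCC returns 0 when a marginal variance is zero (constant
  predictions), and the ratio is clamped to $[-1, 1]$ against rounding.
* The exact Clopper–Pearson interval attached to the MCC maps the
  statistic to a proportion via $(\mathrm{MCC}+1)/2$ with
  $\mathrm{round}(n\,(\mathrm{MCC}+1)/2)$ successes out of $n$, and
  maps the binomial interval back. This is one named, documented
  reading of "an exact binomial interval for the MCC" — the MCC is not
  a binomial proportion, and no distributional claim is implied.
* AUROC is computed by the rank (Mann–Whitney) statistic, equal to
  trapezoidal ROC integration with tie handling; AUPRC by step-wise
  interpolation. Both are support-weighted one-vs-rest averages, the
  averaging rule a single printed value per metric requires.

## Known limitations

* The engine is CPU-bound pure R; it is sized for the tiny backbone and
  desk-scale studies, not for full-resolution training. Larger
  backbones plug in through `backbone_spec()` widths, at proportional
  cost.
* The two-phase calibrated protocol is a small-model necessity; with a
  large pretrained backbone the single-phase protocol of the full-scale
  setting is expected to apply, but this package cannot verify that at
  desk scale.
* The synthetic task is far easier than real radiography; MCC values
  from `synthetic_study()` characterize the pipeline, not the clinical
  problem.
* Statistical significance testing between models and Grad-CAM-style
  localization are out of scope.
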