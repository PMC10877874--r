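---
title: "Methods: edge-output segmentation and multi-indicator diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edge-output segmentation and multi-indicator diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ovadx)
```

ovadx implements two complementary analyses for ovarian cancer data and the
synthetic generators needed to exercise them without clinical data: a fully
convolutional edge-output network that segments tumors in T2-weighted MRI
slices, and a diagnostic pipeline that turns a 25-indicator laboratory panel
into a continuous case score. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
experiments do and do not show.

## The segmentation model

### Architecture

The network has two parts: feature extraction and edge output. Feature
extraction is a residual backbone; with `backbone = "resnet50"` it is the
standard 16-bottleneck-block layout with the last three residual blocks, the
global pooling layer and the fully connected layer removed, because stride-32
feature maps are too coarse to upsample into a useful segmentation. Blocks
are numbered 1–16 in forward order, so truncation keeps blocks 1–13 and the
retained stages end at strides 4, 8 and 16.

Edge-output branches tap the final layers of residual blocks 3, 7 and 13 —
the last block of each retained stage. Each branch first reduces the tapped
feature map to 128 channels with a 1×1 convolution (cutting the cost of what
follows while keeping the feature content), then upsamples to the input
resolution with a transposed convolution whose kernel is initialised to
bilinear interpolation (kernel `2f`, stride `f`, padding `f/2` for an
upsampling factor `f`). The three upsampled maps are concatenated and fused
by two 1×1 convolutions — a channel dimensionality reduction ending in a
single output channel — followed by a per-pixel sigmoid, so the output is a
probability map the same size as the input.

`backbone = "reduced"` builds the same three-tap structure over a shallow
basic-block backbone (default widths 8/16/32, two blocks per stage, strides
1/2/4). It exists so that training experiments run in seconds-to-minutes on
one CPU; every structural contract (three branches, channel reduction,
bilinear-initialised upsampling, two-convolution head) is identical.

Open design points and how they were resolved:

* **Loss attachment.** Side outputs in the edge-output literature sometimes
  carry their own deeply supervised losses. Here the loss attaches to the
  fused head only; the side branches learn through the fusion gradient. This
  is the simpler reading and avoids three extra loss weights.
* **Pre-training.** The backbone accepts a pre-training hook but no weights
  ship with the package; all experiments start from random initialisation
  (He-style normal for convolutions, bilinear for upsampling). Replicating a
  grayscale slice to three channels to reuse stock pretrained weights is a
  documented extension point, not a tested path.
* **Binarization.** Probability maps are thresholded at 0.5 by default; the
  threshold is a parameter everywhere it appears.

### Losses

Training minimises one of three objectives on the probability map `p`
against the binary gold mask `y`:

* **Class-balanced cross-entropy (CBCE).** With `β = |Y−|/|Y|` (the
  background fraction), the loss is
  `−β Σ_{j∈Y+} log p_j − (1−β) Σ_{j∈Y−} log(1−p_j)`. Because tumors occupy a
  small fraction of a slice, plain cross-entropy is dominated by background
  pixels; weighting by the opposite class's frequency equalises the summed
  gradient mass of the two classes.
* **Cross-entropy (CE).** The unweighted sum, for comparison.
* **Dice loss.** `1 − (2Σpy + s)/(Σp + Σy + s)` with smoothing `s = 1`. The
  smoothing constant guards the empty-mask case; probabilities enter
  directly (soft Dice).

Probabilities are clipped to `[1e−7, 1 − 1e−7]` before logarithms; losses
are summed over pixels to mirror their definitions, with an averaging flag
used by the optimizer (Adam is scale-adaptive, so this changes trajectories
only mildly). All three losses are checked against independently coded
double-loop oracles in the test suite.

A practical note from the desk-scale experiments: the Dice loss has a dead
zone — if gradients push the prediction toward the empty mask, `p(1−p)`
vanishes and training cannot recover. At the package's small training
budgets this happens at learning rates below about 5e−3, while higher rates
can overshoot into the same state late in training. Two standard mitigations
are used: the grid experiment runs Adam at 1e−2, where escape from the
degenerate states is fastest, and `train_model()` defaults to best-epoch
checkpoint selection — after each epoch the mean training loss is
re-evaluated with the epoch's final parameters, and the fit returns the
epoch with the lowest value (`keep = "final"` disables this).

### Evaluation

Four measures compare a binarized prediction with the gold standard: DSC
`= 2TP/(2TP+FP+FN)`, sensitivity `= TP/(TP+FN)`, specificity `= TN/(TN+FP)`,
and the Hausdorff distance — the larger of the two directed
furthest-nearest-neighbor Euclidean distances between boundary point sets.
Boundaries are positive pixels with at least one non-positive 4-neighbor (or
on the image edge); pixel spacing defaults to 1. Dataset-level results are
reported as mean ± sd with the sample (n−1) denominator, DSC/Se/Sp in
percent. Two policies close degenerate cases: two empty masks have DSC 1
(perfect agreement, with a warning), and an empty prediction has no defined
Hausdorff distance (dropped from the HD aggregate, with the case count
reported).

### Phantoms and the experiment harness

Because no clinical images accompany the method, training and evaluation run
on synthetic phantoms: an elliptical, ring-shaped (ellipse minus a
concentric half-scale ellipse) or fuzzy-boundary tumor — a Gaussian-blurred
ellipse whose smooth intensity ramp stays in the image while the gold mask
is the ramp thresholded at 0.5 — over a smoothly textured background, with
additive Gaussian noise. The three shapes reproduce the difficulty regimes
segmentation networks are judged on: clean boundaries, topology with a hole,
and blurred demarcation lines. The texture is mean-centered within tumor and
background separately, so `tumor_intensity_contrast` is the exact mean
offset between the regions before noise. Phantoms emulate none of the
physics of real MRI — no bias fields, coil artifacts, partial-volume
effects, or anatomy — so passing results demonstrate that the
implementation learns and measures what it claims, not clinical-grade
performance.

Preprocessing follows the published recipe: min–max normalization to [0, 1]
(a constant image maps to zeros with a warning, since the formula is
undefined there), tumor-centroid-centered ROI crops clamped inside the image
(shifting the window rather than padding preserves true intensities), and
five-fold augmentation. "Rotated by 90° and 180° and flipped up and down" is
read as the variant set {original, rot90, rot180, vertical flip, horizontal
flip} — the only four augmenting transforms that make the dataset exactly
five times its original size.

Two experiments are wired into the harness:

* **Easy-phantom training** (the implementation check): 30 phantoms of 64
  pixels, contrast 0.6, noise 0.05; reduced backbone; CBCE; Adam 5e−3, 20
  epochs, batch 4, 80/20 split. This reaches held-out DSC well above 85% in
  about a minute on one CPU.
* **Loss × ROI-size grid**: 12 phantoms of 320 pixels (contrast 0.65, noise
  0.05) whose tumor semi-axes are 5–9% of the side — a fixed absolute tumor
  size, so that cropping ROIs of 96 and 320 pixels around the tumor centroid
  varies only the amount of background and hence the class imbalance,
  exactly the variable the experiment isolates. Each (loss, size) cell
  trains its own network (10 epochs, batch 1, Adam 1e−2, 2/3 split). At
  these budgets the class-balanced and Dice losses learn the small-ROI
  condition well and lose roughly ten Dice points at 320, reproducing the
  qualitative trend that segmentation quality decreases as ROI size grows;
  plain cross-entropy frequently degenerates to the all-background
  prediction at both sizes under this degree of imbalance — the very
  failure mode class balancing exists to fix. The published absolute values are not
  reproducible — they belong to the unavailable clinical dataset — and the
  package does not attempt a U-net baseline; the comparison harness accepts
  any system's masks (or per-case score tables) through `compare_models()`.

Problem sizes throughout were chosen so the full suite runs in minutes on a
single CPU; they are the package's desk-scale defaults, and every one of
them is a visible, overridable parameter.

## The diagnostic model

### Cohort structure

The synthetic cohort generator emulates the published study population: 185
ovarian cancer cases and three control subgroups (138 other malignant
tumors, 339 benign diseases, 92 healthy examinees). Each subject carries 25
laboratory indicators — the published loadings table lists 25, although the
prose mentions 28 collected indexes; the roster is configurable — plus age,
menopausal status and number of pregnancies.

Indicator values follow a three-factor latent model:
`value = shift + Λ f + ε`, with standard-normal factors `f` representing
tumor-marker/hormone, glucose–lipid and inflammation axes (default loading
0.8 on an indicator's primary factor), residual noise sd 0.6, and a case
mean shift of 0.8 sd (1.5 for CA125, making the single-marker baseline
informative but clearly weaker than the panel). Shift signs are negative for
exactly E2, P, AGR, PA and TC — the five indicators reported to average
lower in cases — and positive elsewhere. Control subgroups receive a scaled
fraction of the case shift on the tumor-marker block (other-malignant 0.3,
benign 0.1, healthy 0), making the other-malignant subgroup the hardest to
separate, as in the published subgroup analysis. Demographics are drawn
independently of the indicators: ages uniform on the published ranges (cases
16–83), menopause probability rising past age 50, pregnancies Poisson with a
lower mean for cases (parity is protective). The generator makes no attempt
at realistic inter-indicator clinical correlations beyond the three-factor
structure, nor at realistic marginal distributions (everything is Gaussian
on an sd scale); it exists so that the pipeline's statistical machinery —
PCA recovery, classifier training, ROC comparisons — can be verified against
a known ground truth.

### Pipeline

1. **Stratified split.** 2/3 training, 1/3 testing, stratified by subgroup
   with a seeded shuffle and a floor rule: `floor(2n/3)` per stratum to
   training. This reproduces the published 123/62 case allocation. (The
   published control split of 378/191 is off by one from any simple rounding
   of 2/3 × 569; the floor rule gives 379/190 and the counts remain
   configurable.)
2. **Z-score standardization** of the 25 indicators, fitted on training rows
   only and applied to all rows, so test data never influence the location
   and scale estimates.
3. **Correlation PCA.** Eigen-decomposition of the training correlation
   matrix (z-scored input makes covariance equal correlation). The three
   leading components are kept; in the synthetic cohort they recover the
   three designed factor axes plus the disease-shift direction. Eigenvector
   signs are fixed by making each component's largest-magnitude loading
   positive, so loading tables are reproducible run to run.
4. **Classifier inputs.** The three component scores, plus the three
   demographics (age and pregnancies z-scored on training rows, menopause as
   0/1). The source method does not state how demographics enter the model;
   appending them unreduced to the component scores is this package's
   choice, recorded here and switchable (`include_demographics = FALSE`).
5. **GA-optimised BP network.** A one-hidden-layer feed-forward network with
   logistic squashing at hidden and output layers (which guarantees the
   stated continuous output in [0, 1]). A real-valued chromosome encodes the
   hidden size (2–20) together with all weights and thresholds; tournament
   selection, arithmetic crossover (rate 0.8), Gaussian mutation (rate 0.05)
   and 2-elitism evolve a population of 40 for 100 generations against the
   validation error on an internal 75/25 split of the training rows. Because
   fitness is deterministic and elites survive unchanged, the best
   validation error is non-increasing across generations — a tested
   contract. The best individual is finally polished by full-batch gradient
   back-propagation on the training portion (log-loss, 200 steps by
   default). None of the GA settings are stated in the source; these
   defaults are ordinary textbook values, all exposed in `ga_config()`.

### Evaluation

Test-row scores feed an ROC analysis: the curve over all distinct score
thresholds, AUC by the Mann–Whitney convention (ties count half), and the
operating point maximising the Youden index `J = Se + Sp − 1` (ties break to
the lowest threshold). Two correlated AUCs on the same subjects — the model
against single CA125 — are compared with the DeLong structural-components
z-test, two-sided normal p. Partition-restricted evaluation handles the two
published secondary analyses: stage tags on cases (each stage evaluated
against all controls) and control subgroups (cases against each subgroup).
In the synthetic cohort the case signal is stage-independent by
construction, so early- and advanced-stage AUCs agree within sampling error
— mirroring the published near-equality, but by design rather than as a
clinical finding.

On default synthetic cohorts the pipeline reaches test AUC above 0.99 —
higher than the published 0.948 because a three-factor Gaussian cohort with
0.8-sd shifts is an easier problem than real patients; the published values
are not reproduction targets. As the case shift is scaled to zero the AUC
degrades monotonically to chance, which is the calibration check that the
classifier learns exactly the injected signal.

## Numerical choices, in one place

* Convolutions are lowered to matrix products via compiled im2col/col2im
  kernels; backpropagation through every layer is hand-derived and verified
  against central finite differences (relative agreement ~1e−8).
* Adam (β₁ 0.9, β₂ 0.999, ε 1e−8) with a fixed learning rate; no schedule.
  The optimizer and schedule are unstated in the source; everything is in
  `train_config()` and recorded in fit objects.
* The printed specificity formula in the source (`FN/(TN+FP)`) contradicts
  its own prose ("true negative rate") and its reported values; the standard
  `TN/(TN+FP)` is implemented.
* Probability clipping 1e−7; Dice smoothing 1; binarization threshold 0.5;
  Hausdorff on 4-connectivity boundaries at unit spacing; sample (n−1)
  standard deviations.
* Every stochastic entry point takes one explicit seed and restores the
  global RNG state on exit; identical seeds reproduce results bit for bit,
  including trained networks.

## Limitations

* Phantoms and Gaussian cohorts validate implementations, not clinical
  claims: no statement about real T2W-MRI or real patients follows from the
  synthetic results.
* The full resnet50 backbone builds and runs forward passes but is not
  trained in tests; desk-scale training uses the reduced backbone.
* Training at ROI 320 with minutes-scale budgets is intentionally
  under-resourced; its role is to expose the imbalance trend, not to show
  the large-ROI condition's ceiling.
* The GA searches a fixed-maximum-width chromosome (hidden size cap 20);
  genuinely variable-length evolution is not implemented.
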