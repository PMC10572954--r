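---
title: "Methods: dataset pipeline, compact CNN, and voting ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dataset pipeline, compact CNN, and voting ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteovote)
```

osteovote implements a three-class osteosarcoma histopathology
classification workflow end to end: dataset preparation with minority-class
balancing, a compact convolutional neural network (CNN) with exact shape and
parameter accounting and a pure-R training engine, a full evaluation-metric
suite, and an adapted majority-voting ensemble with brute-force subset
search. A synthetic-data module makes every stage testable at desk scale
without the external histology collection. This vignette records the model,
the procedures, the parameter defaults, and the numerical choices.

## The classification problem

Hematoxylin-and-eosin (H&E) stained osteosarcoma tiles are labelled with one
of three classes, fixed in this order throughout the package:

| index | class |
|------:|-------|
| 0 | Non-Tumor |
| 1 | Necrotic-Tumor |
| 2 | Viable-Tumor |

The reference collection behind the workflow has 1144 images with class
counts 536 / 263 / 345. `make_count_fixture(scale)` generates a synthetic
dataset with this composition at any scale (counts rounded half-up), so
imbalance handling is exercised on realistic ratios.

## Dataset pipeline

**Splitting.** `split_dataset()` holds out `floor((1 - train_frac) * n)`
images for testing (default `train_frac = 0.8`); 1144 images give 915 train /
229 test. The default split is a simple random partition; `stratified = TRUE`
partitions per class. `carve_validation()` removes a validation fraction from
the training list afterwards. Splitting precedes balancing, so no flipped
copy of a training image can leak into the test set.

**Balancing.** `balance_by_flip()` raises every class to the pre-balance
maximum class count by adding horizontally mirrored copies of randomly chosen
class members. Flips are exact index reversals — bit-identical, involutive
(`flip(flip(x)) = x`) and label-preserving — and every copy records its
source id with provenance `"flipped_copy"`. If a class's deficit exceeds its
size, distinct flips cannot supply enough copies and the function errors
unless `allow_duplicates = TRUE`, in which case sources are drawn in whole
passes over the class plus a without-replacement remainder, making
duplication exactly the minimum the deficit forces. The reference training
composition {422, 208, 285} is such a case: reaching 422 per class adds
214 + 137 copies, and 214 copies from 208 images necessarily repeat 6
sources.

**Preprocessing and augmentation.** `preprocess_image()` resizes bilinearly
to the network input (default 224×224) and scales intensities to [0, 1].
`augment_config()` defines on-the-fly training augmentation: vertical flip
with probability 0.5, rotation uniform in ±20°, and multiplicative brightness
in [1 − 0.2, 1 + 0.2]. Rotation uses inverse-mapped bilinear interpolation
with mirror (reflect) padding so no out-of-tissue background is invented at
the corners.

## Compact CNN

`proposed_architecture()` builds the reference network for 224×224×3 input:
an input batch-normalization layer, then seven blocks of 3×3
same-padding convolution (ReLU) + 2×2 max-pooling with channel widths
32, 32, 64, 64, 128, 128, 256, then flatten, a 512-unit ReLU dense layer,
dropout (default rate 0.5), and a 3-way softmax. Shape and parameter
accounting is closed-form and verified in the tests:

```{r}
spec <- proposed_architecture()
spec$total_params
```

The spatial side length halves through the pooling stack —
224, 112, 56, 28, 14, 7, 3, 1 — and the parameter counts are
$(f^2 C_{in} + 1) C_{out}$ per convolution, $(n_{in} + 1) n_{out}$ per dense
layer, and $4C$ per batch-normalization layer (scale, shift, and the two
moving statistics), totalling 715,311.

**Training engine.** Training is implemented in pure R (`train_learner()`):
im2col convolution, max-pooling with argmax routing for the backward pass,
batch normalization (epsilon 10⁻³, momentum 0.9, moving statistics seeded
from the first batch so small-epoch runs infer sensibly), inverted dropout,
Glorot-uniform initialization, and Adam (learning rate 0.001, β₁ = 0.9,
β₂ = 0.999, epsilon 10⁻⁷) minimizing softmax cross-entropy. Defaults in
`training_config()` — batch size 16, learning rate 0.001 — follow the
reference workflow; the default epoch count is kept small because the pure-R
engine targets desk-scale problems, and the full-scale value (200) is a
config parameter, not a constant. Gradients are verified against central
finite differences through every layer type in the test suite.
`compact_architecture()` provides a scaled-down network of the same layer
grammar for fast experiments.

## Metrics

`metric_report()` computes accuracy, Cohen's kappa (marginal-product expected
agreement), per-class precision/recall/F1/class-accuracy from one-vs-rest
counts, macro/weighted aggregates, multiclass log-loss (probabilities clipped
to [10⁻¹⁵, 1 − 10⁻¹⁵]), and rank-based one-vs-rest ROC-AUC (ties contribute
0.5) with macro and micro averages. Any zero-denominator ratio returns 0 with
a warning rather than NaN. Presentation rounding is half-up via `percent2()`
/ `percent0()`. The suite is cross-checked in the tests against independent
implementations (e1071's kappa, pROC's AUC) and direct-counting oracles.

## Adapted majority-voting ensemble

Each base learner contributes a hard vote — the argmax of its probability
row. `adapted_majority_vote()` picks the class with most votes; when votes
tie, the tie is broken by the summed predicted probability over the tied
classes, and any residual exact tie falls to the lowest class index, making
the result deterministic and learner-order invariant. A strict vote majority
can never be overturned by probabilities. `brute_force_search()` evaluates
every subset of at least two learners (2ᵏ − k − 1 combinations) against
labelled evaluation data and ranks them by the chosen criterion (accuracy by
default), breaking score ties by fewer learners, then higher kappa, then
lexicographic combination name.

```{r}
y <- sample(0:2, 200, replace = TRUE)
preds <- generate_prediction_matrices(3, y, 3, c(0.85, 0.8, 0.9), seed = 5,
                                      learner_ids = c("CNN", "A", "B"))
res <- brute_force_search(preds, y)
res$selected
```

## Synthetic data: what it does and does not emulate

`generate_image_dataset()` draws class-conditional RGB images: a per-class
base colour (an H&E-like palette — light pink stroma, brownish necrotic
debris, dense purple viable tumor), a Poisson number of randomly oriented
filled ellipses in shifted shades ("cell clusters"), and Gaussian pixel noise
clipped to [0, 255]. Class means are separated far beyond the noise scale, so
the classes are learnable by construction and a small CNN verifiably reaches
high validation accuracy within a few epochs. The generator emulates the
*structure* of the task — colour-separable tissue classes, realistic
imbalance, standard image shapes — not histology itself: there is no nuclear
morphology, staining variation, or spatial correlation between tiles, and
accuracy on it says nothing about accuracy on real slides.

`generate_prediction_matrices()` emulates a bank of trained classifiers with
known accuracies: per sample, the predicted label is correct with the
learner's accuracy (wrong labels uniform over the rest), and the probability
row is a Dirichlet-style draw sharply peaked (concentration 20) on the
predicted label, with the argmax guaranteed. Learners are conditionally
independent given the label, which is optimistic relative to real model
banks whose errors correlate.

## Reproducibility and numerical choices

All stochastic functions take a `seed` and restore the caller's RNG state, so
identical arguments give bit-identical output. The end-to-end driver
`run_pipeline()` writes every artifact (manifest, architecture JSON, training
history, predictions, metrics, confusion matrix, search results, config, log)
to its output directory, and `report_run()` re-derives the report tables from
artifacts alone. Numerical choices worth noting: probabilities clipped at
10⁻¹⁵ in the log-loss; probability rows validated to sum to 1 within 10⁻⁶;
batch-norm epsilon 10⁻³; Adam epsilon 10⁻⁷; half-up rounding for all
presentation percentages (base R `round()` is round-half-even).

```{r, eval = FALSE}
cfg <- run_config(output_dir = "run1", seed = 1,
                  synth_counts = c(60, 35, 45), image_size = c(28, 28),
                  architecture = compact_architecture(c(28, 28, 3)),
                  training = training_config(epochs = 4))
res <- run_pipeline(cfg)
overall_table(res$cnn_report)
```
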