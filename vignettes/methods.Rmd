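---
title: "Auditing tumour-patch classifiers with relevance heatmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing tumour-patch classifiers with relevance heatmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Convolutional classifiers for haematoxylin–eosin (H&E) histopathology are
usually judged by patch-level metrics. Those metrics are blind to *how* a
decision is reached, and therefore blind to latent dataset biases: a labelling
convention that ties the label to the patch centre, an artefact that happens
to co-occur with one class, or a tissue type missing from the training data.
`histolrp` implements an explanation-driven quality-assurance workflow for
such classifiers: pixel-wise relevance heatmaps via layer-wise relevance
propagation (LRP), quantitative cell-level evaluation of those heatmaps, and
five controlled experiments that inject and then detect each kind of bias on
fully synthetic, fully annotated H&E-like images.

Everything runs at desk scale on one CPU: 512 px tiles, 64 px patches, and a
small layered CNN. The point is not photorealistic histology but a test bed
in which the ground truth of every cell, region and bias is known exactly.

## Relevance propagation

A trained network's pre-softmax score for the explained class (`cancer` by
default) is redistributed backwards through the layers. For the dense head we
use the ε-rule

$$R_i = \sum_j \frac{z_{ij}}{\sum_{i'} z_{i'j} + \varepsilon\,
\mathrm{sign}\!\left(\sum_{i'} z_{i'j}\right)} R_j,\qquad z_{ij} = x_i w_{ij},$$

with ε = 1, and for convolutions the αβ-rule

$$R_i = \sum_j \left(\alpha\frac{z^+_{ij}}{\sum_{i'} z^+_{i'j}}
+ \beta\frac{z^-_{ij}}{\sum_{i'} z^-_{i'j}}\right) R_j$$

with α = 1, β = 0, so only excitatory evidence is propagated. Max pooling is
winner-take-all (lowest linear index on ties), average and global-average
pooling are treated as convolutions with uniform weights 1/n, and relu /
flatten pass relevance through unchanged. Per-pixel relevance is the sum over
the three colour channels.

Numerical conventions, each of which was a genuinely open choice:

* **Seed quantity.** The backward pass is seeded with a pre-softmax
  quantity, never the softmax probability: the redistribution rules act on
  linear pre-activations, and softmax would couple the two class outputs.
  The default seed is the *logit margin* (target minus other class),
  realised as a virtual output unit whose weights are the difference of the
  two class columns. For a two-class softmax the decision depends only on
  this difference, so its sign cleanly separates evidence for the target
  class from evidence against it; the raw target logit is also available
  (`seed = "logit"`), but for a small from-scratch network both logits can
  be positive almost everywhere, which collapses the sign structure of the
  maps.
* **Biases.** Bias terms enter the denominators (they are part of the unit's
  pre-activation, split by sign for the αβ-rule), but their relevance share
  is absorbed rather than redistributed. This is the one systematic source of
  non-conservation: with zero biases, α = 1/β = 0 conserves the seeded
  relevance exactly (asserted to 1e-6 relative in the tests).
* **Degenerate units.** `sign(0) := +1` in the ε-rule; a unit whose positive
  (resp. negative) pre-activation sum is zero contributes nothing under the
  αβ-rule and its relevance share is absorbed.
* **β sign.** The β term is applied with a plus sign, exactly as in the
  rule's printed form; part of the LRP literature subtracts it instead. With
  the default β = 0 the two conventions coincide, so a non-zero β triggers a
  message.
* **Input layer.** The first convolution uses the same αβ-rule as all others
  (no box-constrained input rule); inputs are scaled to [0, 1] and therefore
  non-negative, which keeps the α-branch well behaved.

## The synthetic tissue model

`generator_spec()` describes H&E-like tiles: an eosin-pink background, two
nucleus populations, and amorphous pale necrosis-like regions that belong to
neither class. Tumour nuclei are larger (13 ± 1.5 px vs 9 ± 1 px) and darker
(haematoxylin purple, mean luminance ≈ 0.2 vs ≈ 0.5), mimicking the
enlarged, hyperchromatic nuclei of malignant cells; a per-tile stain jitter
(sd 0.02) emulates staining variance across slides. Each drawn nucleus
contributes exactly one point annotation at its centroid, and nuclei never
overlap necrotic regions, so cell-level ground truth is exact by
construction. Default density is 300 cells per 512 px tile, so a 64 px patch
holds about four to five cells and plurality labels are stable.

What the generator does *not* emulate: chromatin texture, nucleoli, stromal
architecture, out-of-focus blur, scanner artefacts beyond the single
injected marker, or vessels. Passing experiments therefore demonstrate that
the *pipeline* detects the injected biases under controlled conditions; they
say nothing about classifier quality on real whole-slide images.

Two kinds of study tiles are generated for the experiments:

* **Class-dominant tiles** (training and patch-level testing): the dominant
  class fraction is drawn from U(0.90, 0.98). This emulates how real patch
  datasets are made — patches are cut from large single-class
  region-of-interest annotations, so each patch is nearly pure. At lower
  purity the plurality labels of 64 px patches become intrinsically noisy: an
  ideal colour classifier tops out near 0.87 accuracy at purity 0.75–0.95,
  which is a property of the task, not of any model.
* **Mixed tiles** (cell-level evaluation, tumour fraction U(0.35, 0.60)):
  these represent the heterogeneous annotated evaluation tiles on which
  single-cell recognition is quantified.

## Training protocol

The classifier is a deliberately small layered network —
conv(3→8,3×3)–relu–maxpool(2)–conv(8→16,3×3)–relu–maxpool(2)–
conv(16→32,3×3)–relu–maxpool(2)–flatten–dense. The head is *spatially
resolved* (flatten, not global average pooling) and this is essential at
this scale: a logistic probe on untrained final-stage features separates
marker-corrupted from clean patches at 0.84 accuracy when the probe sees
the spatial cells but only at chance from their global average or maximum.
A global-pooling head therefore makes a 5×5 px class-correlated artefact
unlearnable by any affordable from-scratch protocol (training loss stays
flat at ln 2 even on a task whose only signal is the marker), while the
flatten head learns it to perfection within a few epochs. Global and
average pooling layers remain fully supported by the relevance engine; the
cost of the flatten head is that networks are input-size-specific.
Optimisation is mini-batch SGD with
momentum 0.9 on softmax cross-entropy; the learning rate steps down by a
factor of 10 every 10 epochs; mini-batches are composed at a fixed class
ratio (`round(p·B)` cancer patches per batch, minority class oversampled
with replacement), the protocol's handle for class imbalance; augmentation
is crop-jitter translation (default ±25% of the patch side, an exposed
configuration choice) plus rotations restricted to multiples of 90° to avoid
interpolation artefacts; early stopping is chosen by 3-fold cross-validation
with folds split by tile, never by patch, taking the earliest epoch at the
minimal mean validation error.

The base learning rate defaults to 1e-2. A finetuning setup — adapting a
network that already has useful features — conventionally runs ten times
lower, but this package trains its small network from random initialisation,
and with a 1e-3 base rate the stepped schedule effectively freezes the
network after the first decay while it is still underfitted (held-out
accuracy plateaus near 0.8). At 1e-2 the default task reaches ≥ 0.9 held-out
accuracy within 15 epochs across seeds. The schedule shape, momentum,
maximum of 50 epochs and fold count are unchanged.

The experiments train for 15 epochs with batch size 32 on about 640 patches
from ten tiles — sizes chosen so that one model trains in under two minutes
on a single CPU and the full five-experiment suite stays within roughly a
quarter hour. Cross-validated early stopping is available
(`early_stop_epoch()`) but the experiments use the fixed epoch budget: the
synthetic task converges well inside it and determinism is simpler to
reason about.

## Heatmap assembly and evaluation

For analysis, patch relevance maps are stitched on a non-overlapping grid
and the whole comparison set is normalised by its single global maximum
absolute value, which preserves relative evidence between tiles; for
rendering, one-tenth-overlapping patches with local normalisation give
smoother panels (overlapping contributions are averaged; the display
convention was open and the mean was chosen). Uncovered border pixels are
flagged and excluded from scoring rather than treated as zero relevance.

Cell-level evaluation rectifies the heatmap (negative relevance clamped to
zero), then scores every annotated cell by the mean relevance over the
closed disc of integer pixels within the acceptance radius of its point
annotation. The radius defaults to half the mean annotated cell diameter —
the analogue of half an average cancer-cell diameter at the data's
resolution (about 5 px here). Discs clipped at tile borders keep the mean
over their remaining pixels. Tumour-cell recognition is summarised as a ROC
curve over score thresholds (ties grouped) with trapezoidal AUC; constant
scores yield the chance diagonal, AUC exactly 0.5. Three reference
heatmaps calibrate the scale: all-zeros and all-ones (AUC exactly 0.5) and
i.i.d. uniform [0, 1] noise (AUC 0.5 in expectation; the spread across draws
shrinks with the number of annotated cells; the distribution of the random
baseline was unspecified and uniform was chosen — the mean AUC is
distribution-free, its spread is not). Necrotic regions are scored as whole
structures by their *signed* mean relevance, since the sign is exactly what
distinguishes "mistaken for tumour" from "recognised as irrelevant".

## The five experiments

1. **Feature verification** — train unbiased, check that pooled cell-level
   AUC clearly exceeds all three baselines: the learned evidence sits on
   tumour cells.
2. **Class-sampling ratio** — train at batch ratios 0.5 and 0.8 in favour of
   the cancer class; at 0.8 the cancer recall rises, its precision falls,
   and the heatmaps carry more positive relevance, showing that the
   sampling policy is readable off the explanations without labels. The
   heatmap-level statistic is the mean *net* relevance per held-out patch —
   a patch's total relevance is the classifier's evidence for the class.
   Per-pixel sign fractions (`positive_fraction()`) are reported too, but
   under α = 1/β = 0 with channel-summed maps nearly all negative mass
   cancels pixel-wise, so such fractions saturate and are not monotone in
   the sampling ratio.
3. **Dataset bias** — label patches solely by the centre cell, train without
   translation augmentation, and compare centre-mass profiles of absolute
   relevance against a control trained on random crops of 60% of the patch
   side: the biased model's relevance concentrates at the patch centre.
   Because networks are input-size-specific, the control model is trained
   *and profiled* on its own crop size, and the two profiles are compared
   through relative side lengths (the central ratio: mean |R| inside the
   half-side square over the full-patch mean).
4. **Class-correlated bias** — stamp a 5×5 px single-colour square (top-left
   corner, rows 0–4 × cols 0–4) onto every cancer patch of both splits. The
   marker colour is a saturated erythrocyte-like red-pink: it stays within
   the H&E colour scheme, but it must be distinct from the narrow synthetic
   background palette, because a colour numerically identical to the
   background carries no learnable signal at all. This experiment runs on
   *mixed* tiles: plurality labels of heterogeneous patches cannot be fit
   perfectly from morphology (an ideal colour classifier tops out near
   0.85), so the marker is the only route to near-perfect accuracy — the
   shortcut regime the experiment is designed to expose. The model's test
   accuracy rises far above the morphological ceiling (≥ 95%; the residual
   errors are morphology-driven false positives the small network cannot
   fully suppress), and for most corrupted patches the argmax 5×5 block of
   relevance overlaps the marker. Trained convolutional features respond
   most strongly to the marker's *boundary*, so the peak block straddles
   the marker's edge rather than coinciding with the top-left block
   exactly; the verdict counts argmax blocks intersecting the marker
   (chance rate about 2%). Class-mean heatmaps show the same corner
   signature for the corrupted class only. Whether from-scratch SGD locks
   onto the marker at all is initialisation-dependent — an unlucky run
   settles in the morphology-only basin and plateaus at its ceiling — so
   the experiment uses up to four seeded random restarts and accepts the
   first run whose *training* accuracy reaches 0.995, a level only the
   marker pathway can deliver; test data plays no part in the selection.
5. **Sampling bias** — exclude every patch touching necrosis from training;
   on held-out necrotic regions the biased model produces positive
   tumour-evidence on more regions and with visibly larger spread than the
   model trained on the comprehensive dataset, whose region means stay
   near zero. Verdict thresholds ("majority" = 50%, region counts) are
   exposed in the experiment configuration.

Each `run_*()` returns an `experiment_report` carrying the full
configuration snapshot and seed, so any report can be regenerated exactly;
verdict flags encode the qualitative claims as explicit inequalities.

## Known limitations

* The CNN is a surrogate, far smaller than production architectures; LRP
  rule behaviour on batch-norm or residual connections is out of scope.
* ε- and αβ-rule relevance is not implemented for strided or padded
  convolution variants beyond valid padding, which the default architecture
  does not use.
* The synthetic task is colour/size-separable by design; conclusions about
  texture-driven discrimination do not transfer.
* Region relevance comparisons across models rely on per-model global
  normalisation; absolute relevance magnitudes are not comparable across
  differently trained networks.
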