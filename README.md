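# histolrp

Explanation-driven quality assurance for histopathology patch classifiers,
at desk scale and fully synthetic.

Convolutional classifiers for haematoxylin–eosin (H&E) tumour-patch
discrimination are usually judged by patch-level metrics such as the
weighted F1 score. Those metrics cannot tell *why* a model decides, and so
cannot detect latent dataset biases — a labelling rule tied to the patch
centre, an artefact correlated with one class, a tissue type missing from
training. `histolrp` implements the complementary, explanation-based audit:

* **Layer-wise relevance propagation (LRP)** for a small layered CNN. The
  target class's pre-softmax evidence (by default the two-class logit
  margin) is redistributed backwards: the ε-rule for the dense head,

  R_i = Σ_j z_ij / (Σ_i′ z_i′j + ε·sign(Σ_i′ z_i′j)) · R_j,  z_ij = x_i w_ij, ε = 1,

  and the αβ-rule (α = 1, β = 0) for convolutions,

  R_i = Σ_j ( α·z⁺_ij / Σ_i′ z⁺_i′j + β·z⁻_ij / Σ_i′ z⁻_i′j ) · R_j,

  with winner-take-all max pooling and pass-through relu/flatten. Positive
  relevance supports the `cancer` class, negative contradicts it.
* **A seeded synthetic H&E generator**: eosin-pink tiles with two nucleus
  populations separable by size and haematoxylin intensity, necrosis-like
  regions belonging to neither class, per-cell point annotations, and
  injectable biases (centre-cell labelling, a 5×5 px corner marker,
  necrosis exclusion). Every pixel of ground truth is known.
* **Cell-level quantitative evaluation**: each annotated cell is scored by
  the mean rectified relevance in a disc around its point annotation, and
  tumour-cell recognition is summarised as ROC/AUC against zeros-, ones-
  and random-heatmap baselines (all at chance, AUC 0.5).
* **Five controlled experiments** (`run_feature_verification`,
  `run_sampling_ratio`, `run_dataset_bias`, `run_class_bias`,
  `run_sampling_bias`) that train models under each bias and verify that
  the heatmaps expose it.

The training protocol is mini-batch SGD with momentum, a learning rate
stepped down ×10 every 10 epochs, ratio-controlled batch composition
(minority oversampling), translation/rotation augmentation, and 3-fold
cross-validated early stopping with folds split by tile.

## Worked example

```r
library(histolrp)

spec  <- generator_spec()                      # 512 px tiles, 64 px patches
tile  <- generate_tile(spec, seed = 1)
tile
#> <tissue_tile tile_0000000001> 512x512 px, 300 cells (108 tumour), 2 region(s)

## train a classifier on class-dominant tiles, explain held-out mixed tiles
cfg   <- experiment_config(seed = 1)
rep   <- run_feature_verification(cfg)         # a few minutes on one CPU
rep
#> <experiment_report 'feature_verification'> (seed 1)
#>   auc_above_zeros                               PASS
#>   auc_above_ones                                PASS
#>   auc_above_random                              PASS
round(rep$pooled_auc, 3)
#> [1] 0.958
round(rep$patch_metrics$weighted_f1, 3)
#> [1] 0.934
round(unlist(rep$baselines$random), 4)
#> mean     sd
#> 0.5018 0.0203
```

`pooled_auc` is the area under the ROC curve for recognising individual
tumour cells from the rectified relevance heatmap — 0.96 means the
explanation mass sits on the cells a pathologist would point at, far above
the 0.5 of constant or random heatmaps. The weighted F1 (0.93) is the
ordinary patch-level performance on held-out tiles.


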