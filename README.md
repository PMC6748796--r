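# crowdmask

Concordance analysis of crowdsourced histology region annotations.

Producing pixel-exact ground truth for semantic segmentation of histology
images usually means asking many people — senior pathologists (SP), junior
residents (JP) and trained non-pathologists (NP) — to outline tissue regions
as labeled polygons, having the seniors patch the juniors' work with
correction overlays, and tracking how much annotators disagree. `crowdmask`
is an R package for the quantitative side of such a study:

* **Annotation model.** Class taxonomies with a *default* tissue class
  (stroma, "defined by absence of annotations"), participants with
  experience tiers, ROIs, polygon annotations, and JSON/PNG readers and
  writers for all of them.
* **Mask rendering.** Scanline polygon rasterization onto ROI grids
  (pixel-center rule, boundary-inclusive, nonzero winding), default-class
  fill, later-drawn-wins overlap resolution, correction-overlay patching,
  and region extraction back out of masks.
* **Discordance.** The pooled multi-class Dice discordance between masks
  $I$ and $J$ over class channels $c = 1..N_c$,

  $$\Delta_{i,j} = 1 - \frac{2\sum_c |I_c \cap J_c|}{\sum_c (|I_c|+|J_c|)} \in [0,1],$$

  pairwise discordance matrices over a cohort, per-class (binary)
  discordance, pre/post-correction discordance and pixel-wise group
  disagreement maps.
* **Cohort analysis.** Tier-pair distributions, Mann–Whitney and Wilcoxon
  signed-rank tests with exact small-sample enumeration (ties included),
  biclustered heatmap ordering and classical MDS embedding of the
  discordance matrix.
* **Synthetic annotators.** A seeded generator of ground-truth tissue
  scenes and multi-tier annotator cohorts with boundary jitter, class
  confusion and region-miss error structure, plus simulated reviewer
  corrections — the whole pipeline runs without any slide archive.
* **Segmentation evaluation.** Per-class pixel ROC AUC (midrank ties),
  Dice, accuracy, micro/macro AUC, confusion percentages, patch extraction
  with purity filtering, shift-crop augmentation, and a learning-curve
  harness (macro AUC vs number of training slides, strict train/test
  separation by institute) with a shallow glmnet baseline classifier.

## Worked example

Simulate a 12-participant study (3 SP / 3 JP / 6 NP with tier-graded error
models) on 10 evaluation ROIs, render everyone's masks, and analyse
concordance:

```r
library(crowdmask)

bundle <- simulate_cohort(roster = default_roster(), n_eval_rois = 10, seed = 1)
masks  <- cohort_masks(bundle)
dm     <- pairwise_discordance(masks, participants = bundle$participants)
dm
#> <discordance_matrix> 12 participants, 66 unique pairs (pooled, classes: tumor,
#>   stroma, lymphocytic_infiltrate, necrosis, blood_vessel, adipose, blood, plasma_cells)
#>   discordance: median 0.328, range [0.124, 0.495]

tier_pair_distributions(dm)[, c("pair_class", "n_pairs", "median", "sd")]
#>   pair_class n_pairs median      sd
#> 1      JP-JP       3  0.311 0.04192
#> 2      JP-NP      18  0.358 0.04296
#> 3      NP-NP      15  0.391 0.04733
#> 4      SP-JP       9  0.204 0.03495
#> 5      SP-NP      18  0.308 0.03956
#> 6      SP-SP       3  0.125 0.00102
```

Senior pairs agree best (median 0.125), mixed pairs sit in between (0.308)
and non-pathologist pairs disagree most (0.391) — the bias/variance
structure a real mixed-experience cohort shows. Rank-test the shift and
embed the matrix:

```r
td <- tier_pair_distributions(dm)
rank_test_unpaired(td$values[[which(td$pair_class == "SP-SP")]],
                   td$values[[which(td$pair_class == "NP-NP")]],
                   alternative = "less")$p.value
#> 0.00458

mds_embed(dm)
#> <mds_embedding> 12 participants, stress 0.5311
plot(dm)                                            # biclustered heatmap
plot(mds_embed(dm), tiers = bundle$participants$tier)
```

Per-class discordance separates easy from hard tissue: tumor boundaries
disagree a little, rare classes (here blood vessels, which NPs miss half
the time) disagree a lot. Segmentation predictions are scored pixel-wise
with `evaluate_prediction()` / `class_auc()`, and `learning_curve()`
measures how classifier accuracy grows with the number of annotated
training slides.

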