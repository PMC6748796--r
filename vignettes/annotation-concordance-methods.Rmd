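---
title: "Methods: crowdsourced annotation masks and concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crowdsourced annotation masks and concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdmask)
```

## The problem

Semantic segmentation models for histology need exhaustively labeled images:
every pixel of a region of interest (ROI) assigned to a tissue class. One
practical way to produce such data at scale is *structured crowdsourcing*: a
mixed cohort of senior pathologists (SP), junior pathology residents (JP) and
trained non-pathologists (NP) each outline tissue regions as labeled polygons
in a web slide viewer, seniors review and patch the juniors' work with
correction overlays, and inter-participant agreement is monitored on a shared
set of evaluation ROIs. `crowdmask` implements the quantitative side of such
a study: polygon-to-mask rendering, a multi-class discordance statistic and
its cohort-level analysis, pixel-level scoring of segmentation predictions,
and a synthetic annotator simulator so that the entire pipeline is testable
without any slide archive.

## From polygons to label masks

Annotations are closed polygons in ROI-local, 0-based, pixel-center
coordinates (`x` = column, `y` = row). Rendering follows three rules:

* **Default class.** Pixels covered by no polygon receive the taxonomy's
  default class — stroma in breast tissue, where it is the most prevalent
  component and is deliberately "defined by absence" so that annotators only
  outline the other tissues. Label code 0 is reserved for pixels outside the
  ROI and is excluded from every statistic.
* **Later-drawn wins.** Within one participant's annotation stream, draw
  order is the only precedence signal available, so overlapping polygons are
  resolved in its favor. A polygon of class A inside a polygon of class B
  simply overwrites it — there is no explicit hole topology, matching
  overlay semantics.
* **Corrections outrank originals.** Expert correction overlays are patched
  on top of the rendered mask (`apply_corrections()`); pixels outside the
  correction polygons are untouched, which the test suite asserts as a
  conservation property.

A pixel belongs to a polygon when its center lies inside under the nonzero
winding rule (even-odd is available as a policy switch; the two coincide for
simple polygons), and centers exactly on an edge count as inside. The
rasterizer is a scanline algorithm with an explicit boundary pass, and the
test suite pins it pixel-for-pixel to an independent point-in-polygon oracle.
Region extraction (`extract_regions()`) inverts rendering: 8-connected
components of each non-default class are traced along the 0.5 level set of
their indicator, which runs along pixel borders. Traced polygons re-render
to at least 99% pixel agreement on smooth scenes; where a pixel-exact cover
is required (reviewer corrections), traced contours are verified by
re-rasterization and replaced by per-row run rectangles when ambiguous.

## The discordance statistic

For two masks $I, J$ viewed as binary channels $I_c, J_c$ over a class
subset of size $N_c$, discordance is one minus the pooled Dice coefficient:

$$\Delta_{i,j} \;=\; 1 \;-\; \frac{2\sum_{c=1}^{N_c} |I_c \cap J_c|}
{\sum_{c=1}^{N_c} \left(|I_c| + |J_c|\right)} \;\in\; [0, 1],$$

with 0 meaning no discordance. Design choices worth stating:

* **Pooling across ROIs.** The default aggregation sums the numerator and
  denominator over all evaluation ROIs before taking the ratio — the literal
  reading of the statistic applied to stacked channels, and algebraically
  identical to evaluating it on concatenated masks (asserted numerically in
  the tests). A per-ROI median is available as `aggregation =
  "per_roi_median"`.
* **Vacuous denominators.** When neither mask contains any pixel of the
  subset, the value is defined as 0 (vacuous agreement) with a `vacuous`
  attribute rather than `NaN`, keeping discordance matrices total without
  losing the information.
* **The default class is an ordinary channel** whenever it is listed in the
  subset; the `"all"` preset is every non-meta class, `"tumor"` the binary
  view.
* Single-class discordance is exactly one minus the Sørensen–Dice
  similarity of the binary channels; a class present in only one mask gives
  1, matching the intuition that a wholly missed region is maximal error.

## Cohort analysis

Unique participant pairs are grouped by unordered tier pair (SP–SP, SP–NP,
NP–NP, ...), forming a partition of the $\binom{n}{2}$ pairs. Distribution
comparisons use rank tests implemented in-package because their contract
requires exact small-sample p-values *under ties*: the Mann–Whitney test
enumerates all group assignments conditional on the observed midranks when
$n_1+n_2 \le 12$, and the Wilcoxon signed-rank test convolves the doubled
midranks of nonzero differences when $n \le 15$ (zero differences are
dropped and counted). Larger samples use the tie-corrected,
continuity-corrected normal approximation; against exact enumeration its
one-sided error is below $10^{-2}$ at $6+6$ observations and below $0.02$
even at $3+3$ (measured exhaustively in the tests). All p-values are
two-sided by default with a sidedness argument.

The biclustered heatmap order comes from average-linkage hierarchical
clustering of Euclidean distances between discordance profiles (matrix
rows); participants are pre-sorted by id so the leaf order is deterministic
and invariant to input order. The 2-D embedding is classical (Torgerson)
MDS — spectral, deterministic, no random initialization — with negative
eigenvalue mass and Kruskal stress-1 reported. Discordance matrices are
generally non-Euclidean, so stress values around 0.3–0.5 are expected and
the embedding is read qualitatively (proximity = concordance), exactly as a
study would read it.

## The synthetic annotator cohort

The simulator stands in for the raw study data and encodes the three
dominant annotation error types: imprecise boundaries, region
misclassification, and missing annotations for non-predominant classes.

* **Scenes.** A ground-truth ROI is a thresholded smoothed-noise blob
  process: per mixture class, a Gaussian random field (blur scale
  `region_scale/3`) claims the class's target fraction of still-unassigned
  pixels, the remainder staying stroma; components below `min_region_px`
  (default 16 px) melt back into stroma, since annotators do not trace
  few-pixel slivers. Small rare-class disks are then injected. Defaults —
  96×96 px, tumor 0.35 / lymphocytic infiltrate 0.15 / necrosis 0.10, two
  rare blobs of radius 4 — emulate tumor-dense ROI selection at desk scale.
  (Real evaluation ROIs are orders of magnitude larger; sizes here were
  chosen so a full cohort simulates in seconds, and every concordance
  statistic is scale-free.)
* **Annotators.** Each truth polygon is dropped with a tier-dependent miss
  probability keyed to the *class's* tier (rare classes get missed, the
  paper's dominant NP failure mode), relabeled by sampling a row-stochastic
  confusion matrix, then jittered: vertices resampled at `vertex_spacing`
  (3 px) and displaced along vertex normals by circularly smoothed Gaussian
  noise rescaled to sd `boundary_jitter_sigma`. Jitter lives in polygon
  space, so the same model serves any resolution. Self-intersecting draws
  are rejected and redrawn with progressively damped amplitude — an
  important detail: falling back to the unjittered boundary would silently
  make high-curvature regions perfect and compress the NP–NP vs SP–NP
  contrast.
* **Default roster.** 3 SP / 3 JP / 6 NP with jitter 1/2/4 px,
  non-predominant miss 0.05/0.2/0.5, challenging miss 0.2/0.6/0.9 and mild
  confusion toward stroma (0/0.02/0.05). The SP-1px/NP-4px/miss-0.5
  calibration is the configuration under which tier recovery is asserted;
  the rest grades JPs between the extremes.
* **Corrections.** Connected components (4-connected, for exact tracing) of
  the annotator-vs-truth disagreement become correction polygons labeled
  with the truth class, each dropped with probability `reviewer_miss`
  (default 0.1). A noise-free reviewer provably restores truth exactly.
* **Study design.** `simulate_cohort()` gives every participant all
  evaluation ROIs (no reviewer feedback there, keeping the concordance
  analysis unbiased) and partitions core ROIs round-robin, with slides
  assigned round-robin to simulated institutes.

What passing tests do *not* show about real data: the simulator has no
histologic texture (classes are flat noisy colors), no correlated errors
from shared training, no intra-participant variability, and no
"challenging" tissue classes by default. Tier recovery on this cohort
demonstrates that the *pipeline* orders error structure correctly, not that
real cohorts behave this way.

## Segmentation evaluation and the learning curve

Predictions are per-class score planes; the argmax defines the hard mask.
Per-class one-vs-rest pixel AUC uses the midrank statistic (exactly the
$O(n^2)$ pairwise comparison with ties counted half, asserted against that
oracle), label-0 pixels excluded, and a class absent from the truth reported
as `NA`, never 0. Micro AUC pools all pixel-class score/indicator pairs;
macro is the unweighted class mean; the confusion matrix is expressed as
percentages of total in-ROI pixels and sums to 100. Evaluation collapses
taxonomies to the five-way scheme tumor / stroma / inflammatory / necrosis /
other (mapping overridable).

The learning-curve harness tests the *experimental design* — seeded slide
sampling without replacement, strict train/test separation by institute,
macro-AUC aggregation — with a deliberately shallow baseline classifier:
pooled color and gradient features into a ridge-regularized multinomial
linear model (`glmnet`). Synthetic RGB renderings give each class a distinct
noisy color plus a per-slide stain-like channel shift, so generalizing
across slides genuinely requires seeing several of them, and mean macro AUC
rises steeply from 2 to 8 training slides before saturating — the asymptotic
shape such experiments show. Classes too small or impure to yield training
patches (necrosis at default purity 0.8, and "other") score 0 everywhere
and anchor their one-vs-rest AUC near 0.5, which is the realistic rare-class
penalty, not a defect. Deep segmentation networks are deliberately out of
scope.

## Numerical conventions

* Coordinates: 0-based pixel centers, `x` = column, `y` = row, ROI-local;
  slide-frame conversion is addition of the ROI origin.
* Label codes: taxonomy files are authoritative, no automatic numbering;
  code 0 reserved; codes fit 8-bit indexed PNG.
* Boundary pixels (centers exactly on a polygon edge, tolerance $10^{-9}$)
  are inside.
* Degenerate zero-area polygons rasterize to an empty mask with a warning,
  not an error.
* All stochastic components take explicit integer seeds and restore the
  caller's RNG state; equal seeds give byte-identical cohorts.

## A worked example

```{r example, eval = FALSE}
bundle <- simulate_cohort(roster = default_roster(), n_eval_rois = 10,
                          seed = 1)
masks <- cohort_masks(bundle)
dm <- pairwise_discordance(masks, participants = bundle$participants)
tier_pair_distributions(dm)[, c("pair_class", "n_pairs", "median")]
plot(dm)                      # biclustered heatmap
plot(mds_embed(dm), tiers = bundle$participants$tier)
```

## Known limitations

* Region extraction returns one outer polygon per connected component;
  components with internal holes are approximated by their outer boundary
  (draw-order layering recovers nesting on re-render, to the 99% agreement
  asserted, but not exactly).
* Classical MDS can place non-Euclidean discordance structure imperfectly;
  stress is reported so users can judge.
* The annotation JSON dialect is a faithful stand-in for a slide-server
  export, not a validated adapter for any specific platform.
* No multiple-testing correction is applied across class-stratified tests;
  reported p-values are raw.
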