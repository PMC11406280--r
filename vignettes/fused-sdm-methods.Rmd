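---
title: "Methods: fused imagery-climate species distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused imagery-climate species distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modeling choices behind **fusedsdm**: what is
being estimated, the assumptions each stage makes, the parameters that
matter, and what the simulated-world test suite does and does not
demonstrate about real data.

## The problem and the model

Citizen-science occurrence archives record where someone saw a species —
presence-only, spatially biased, and incomplete. fusedsdm treats joint
species distribution modeling as **multilabel classification**: each
curated observation anchors a location with a set of species known to occur
there, a 4-band (RGB + near-infrared) aerial image patch centered on it, and
a vector of bioclimatic covariates sampled at it. A neural network maps
these inputs to an independent presence probability per species,

$$\hat p_{is} = \sigma(z_{is}),$$

with no normalization across species: communities are sets, not categories.
Three parallel output heads predict species, genus, and family memberships
simultaneously; the coarser ranks act as a phylogenetically informed
auxiliary signal that shares gradient information among related, and often
co-ranging, species.

The fused architecture has two branches:

* an **image encoder** — a residual convolutional network over the 4-channel
  patch: a stride-2 stem convolution, residual stages that double in width
  while halving resolution, and global average pooling. Convolutions use
  Kaiming-style initialization; the last batch-normalization scale in every
  residual branch starts at zero, so each block is exactly its shortcut at
  initialization and depth does not impede early optimization.
* a **climate perceptron** — fully connected layers
  $B \to 1000 \to 1000 \to \text{dropout}(0.25) \to 2000 \to 2000$ with
  rectifier activations (the reference widths; all configurable).

The encoder's pooled features and the perceptron's final hidden activations
are concatenated and passed through one fully connected fusion layer before
the three rank heads. The two branches see information at very different
spatial grains — meters for imagery, a kilometer for climate — which is
precisely why fusing them outperforms either alone: fine-scale land cover is
invisible to climate, and broad climatic gradients are invisible to a single
image patch.

## Curation of occurrence data

All geometry runs in one projected, meter-unit CRS (lon/lat inputs are
reprojected on read through an exactly invertible transverse Mercator
centered on the data). The curation defaults are:

| step | default | meaning |
|---|---|---|
| coordinate uncertainty | ≤ 120 m | drop imprecise records at read time |
| deduplication | 150 m | one record per species per neighborhood; greedy in stable input order, first record wins |
| confined-species filter | 256 m | drop species whose records all lie within 256 m of their centroid (no range signal at image scale) |
| neighbor imputation | 256 m | add species observed within the image footprint to an anchor's label set |
| minimum count | 500 | drop species with fewer label-set memberships **after** imputation |

Two geometric readings were open and are fixed here: "confined within a
radius" means *within the radius of the species centroid* (a concrete,
testable rule; the pairwise-diameter alternative would be about twice as
permissive), and "overlapping radius" for imputation means *center distance
at most 256 m*, i.e. overlapping square image footprints. Imputation runs on
the deduplicated set, so removed duplicates cannot re-enter label sets, and
anchors are never merged.

## Leakage-free partitioning

Climate pixels are roughly a kilometer across, so two observations up to
~1.2 km apart can share an identical climate input. Both splitters therefore
enforce a **1,300 m exclusion**:

* the **uniform split** accepts a random candidate only when its nearest
  non-overlapping neighbor (beyond 256 m) is farther than 1,300 m, and drags
  every footprint-overlapping anchor into the test set with it;
* the **latitudinal folds** hold out consecutive one-degree bands
  (half-open `[lo, hi)`, snapped to integer degrees covering the data) and
  drop training anchors within 1,300 m of the band envelope.

The default uniform test fraction, 1.88%, mirrors the realized fraction of
the statewide reference split; it is a target, not a constraint. Split
geometry is verified in the test suite by brute-force pairwise distance
checks on 1,000-anchor fixtures.

## The sampling-aware loss

Most locations list only a fraction of the species actually present, and
that fraction varies with how heavily a place is surveyed. Plain binary
cross-entropy has two corresponding defects: with thousands of species and a
handful of presences per observation, absences dominate the gradient; and it
treats every absence as equally trustworthy. The sampling-aware binary
cross-entropy addresses both:

$$L = \frac{1}{N}\sum_i \Big[-\frac{1}{|P_i|}\sum_{s\in P_i}\log \hat p_{is}
\;-\; c_i\,\frac{1}{|A_i|}\sum_{s\in A_i}\log(1-\hat p_{is})\Big],$$

mean-balancing present and absent terms within each observation and scaling
the absent term by an estimated per-location survey completeness
$c_i \in (0,1]$. Completeness is a richness-quantile ratio:
$c_i = \min(1,\, n_i/n_{\mathrm{ref}})$, where $n_i$ is the number of
distinct species recorded within 256 m of anchor $i$ and
$n_{\mathrm{ref}}$ is the 95th percentile of $n_i$ over all anchors — a
location that has yielded as many species as the best-surveyed places is
treated as fully surveyed. At $c_i = 0$ the gradient with respect to every
absent-species logit vanishes exactly; at $c_i = 1$ with balanced label sets
the loss reduces to (twice) the standard mean binary cross-entropy. Both
identities, and finite-difference agreement of the analytic gradient, are
asserted in the tests at tight tolerances.

Training uses seeded mini-batch Adam (reference protocol: 13 epochs);
after every epoch the mean per-species AUC_ROC on the monitoring split is
recorded and the best epoch's weights are kept. The learning-rate sweep
utility interprets a "stepwise sweep in increments of 0.5" multiplicatively:
half-decade steps from 5e-6 to 1e-1, the only reading that spans that range
in a sensible number of steps.

## Evaluation suite and baselines

Metrics come in three families, reported per species and per observation
with medians and interquartile ranges: thresholded binary metrics
(precision/recall/F1 at 0.5, plus presence accuracy — the fraction of true
(observation, species) pairs called present), discrimination metrics
(AUC_ROC by the Mann–Whitney construction with ties counted one half;
AUC_PRC by the step-wise average-precision construction), and ranking
metrics (top-K with ties broken by ascending species index; mean average
precision). Species with a single observed class have undefined AUC and are
excluded from aggregation; a species with no predicted presences gets
precision 0 by convention, which keeps degenerate baselines comparable.

Two data-independent baselines calibrate the suite. The *random* baseline
draws scores from a standard normal, maps them through the logistic, and
averages metrics over ten trials: median per-species AUC ≈ 0.5, top-100 of
2,221 species ≈ 100/2221 ≈ 0.045, per-observation recall at 0.5 ≈ 0.5. The
*frequency* baseline scores every species by its training frequency rescaled
linearly to [0.001, 1]; constant columns give per-species AUC exactly 0.5
under the tie convention. `scripts/acceptance.R` recomputes all four
quantities from scratch.

## Prediction maps and community change

`predict_map()` slides the prediction window across the imagery at a fixed
stride, assigning each window's probabilities to the cell georeferenced at
its center (stride 50 on 1 m imagery ⇒ 50 m output grid). Windows are not
overlap-averaged: one window, one cell, which keeps the operator linear-time
and matches the strided-convolution reading of map generation.

Two change statistics summarize the resulting S-vector fields:

* **spatial community change** — per cell, the mean Euclidean norm of the
  difference to its (up to) eight neighbors; an edge detector over community
  composition. Border cells average over existing neighbors rather than
  padded ones, because padding would invent communities. Eight neighbors
  (not four) are used, following the stated neighborhood.
* **temporal community change** — the per-cell Euclidean distance between
  two dates' probability stacks.

The raw-imagery null baselines z-score each band, block-average to the
analysis cell size, and apply the same two operators to band vectors.

## The simulated world

The generator builds the full causal chain the pipeline assumes: smooth
Gaussian-field environmental bands (climate analogue), a fine-scale
categorical land-cover layer visible *only* in the imagery texture, species
whose niches load on environment, land cover, or both
(`landcover_frac = 0.5` by default), presence thresholded to a target
prevalence in [0.05, 0.4], and occurrence sampling driven by a smooth,
optionally quadrant-concentrated effort field with per-species
detectability. Key defaults: 48×48 cells of 256 m, 8 imagery pixels per
cell, 19 environmental bands, 4 land-cover classes, texture noise SD 0.05.
All randomness flows from one seed; worlds are bit-for-bit reproducible.

The information split is deliberate: because land cover never enters the
environmental bands, a climate-only model *cannot* learn half the species,
and an image-only model cannot learn the other half — making the
fused-versus-single-branch ordering identifiable rather than accidental.

What the simulator does **not** emulate: phenology and seasonal imagery,
sensor noise and registration error, taxonomic misidentification,
non-stationary niches, and the extreme rarity tail of real archives.
Passing recovery tests therefore demonstrate that the implementation learns
what its inputs contain under the stated biases — not that any particular
accuracy will transfer to a real survey.

## Numerical choices and problem sizes

* Image reflectances live in [0, 1] (integer rasters divided by the dtype
  maximum); climate is standardized per band with population-SD convention.
  A constant climate band is a fatal error rather than a silent zero-SD.
* Raster cells are half-open; a point on a shared edge belongs to exactly
  one pixel. Edge anchors whose patch would leave the raster are dropped,
  not padded.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.1) at evaluation; dropout is disabled at
  evaluation, so inference is deterministic for fixed weights.
* Ranking ties break by ascending species index; greedy curation ties break
  by input order. Both choices exist purely for reproducibility.
* The test suite trains desk-scale models: 40×40-cell worlds, 6
  environmental bands, 12–32 species, 16 px patches, width-8 encoders,
  ≤ 10 epochs — sizes chosen so the full end-to-end recovery experiment
  (curation → split → fused training → strided map → truth AUC) completes
  in a few minutes on one CPU while still exercising every code path at
  realistic signal-to-noise.
* The loss-comparison experiment (sampling-aware vs. plain BCE) uses a
  32-species world: within-observation class imbalance is the pathology the
  loss addresses, and it only materializes when observed label sets are
  small relative to the species pool.

## Known limitations

The reference residual encoder here is a compact, faithful residual network
rather than a re-implementation of a specific published backbone; its
contract — 4-channel input, residual stages, stated initialization, three
rank heads — is what the architecture comparisons rely on. Training is
single-threaded CPU R; it is meant for methodological work and desk-scale
experiments, not statewide production runs. The completeness estimator is a
richness-quantile proxy; where survey effort correlates with true richness
it will conflate the two. Pearson correlation helpers use ordinary
inference; spatially corrected tests are out of scope.
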