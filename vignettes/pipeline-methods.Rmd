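---
title: "Methods: morphometric identification of batch-imaged pitfall specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric identification of batch-imaged pitfall specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Pitfall-trap surveys produce batches of specimens per trapping event.
`pitfallID` identifies them from pre-extracted feature vectors: each
specimen is segmented out of a dorsal and a ventral batch photograph,
measured, and represented by 68 continuous variables. Classifiers are
trained on species labels only; because the taxonomy is properly nested,
species-level predictions are *lifted* to any higher rank (genus,
tribe, ...) to score identifications at coarser resolution without
retraining — the hierarchical classifier. The alternative, a single-level
classifier retrained on labels at each rank, is also implemented for
comparison.

The statistical assumptions are modest: class-conditional feature
distributions that are roughly unimodal on the standardized scale (LDA
and naive Bayes make this explicit; KNN, random forests and the neural
network do not), and a taxonomy in which each species has exactly one
ancestor per rank. The taxonomy's rank ladder is configurable; the
default is six ranks (species, group, genus, subtribe, tribe, subfamily).
Surveys that track an additional level can simply supply a seven-column
taxonomy; nothing in the code assumes six.

## Imaging measurements

Images are 8-bit RGB rasters of dark specimens on a light background at a
known resolution (pixels per mm; the defaults assume 12 px/mm).
Coordinates are 0-based and row-major with the origin at top-left;
bounding boxes are half-open. Choices that matter:

* **Thresholding.** The default is a global Otsu threshold on luminance
  with dark-object polarity, which needs no operator; a manual
  per-channel band mode is kept for parity with interactive colour
  thresholding. Selecting more than half the image as foreground warns of
  inverted polarity; an empty foreground is an error.
* **Connectivity.** Regions are 8-connected components (diagonally
  touching pixels merge), with components below `min_area_px` discarded
  as debris. Labeling runs EBImage's 4-connected labeller plus a
  union–find merge of diagonal contacts.
* **Perimeter.** Chain-code length around the traced boundary with the
  Vossepoel–Smeulders corner correction (0.980 per axial step, 1.406 per
  diagonal, −0.091 per direction change). This estimator is in the same
  family as the particle-analysis convention the pipeline emulates and is
  accurate to under 1% on digitized convex shapes; circularity is capped
  at 1.
* **Feret diameters and solidity.** Computed on the convex hull of pixel
  *corners* (each pixel contributes its four unit-square corners), so the
  hull area bounds the pixel count and solidity of a convex region is
  exactly 1; max caliper by pairwise hull distances, min caliper by
  rotating calipers over hull edges.
* **Moment ellipse.** Major/minor axes are `4 * sqrt(eigenvalue)` of the
  second-order central moment matrix with a + 1/12 diagonal term for the
  unit-square pixel extent (keeps thin regions non-degenerate); the
  orientation is reported in degrees, 0–180, x-axis zero, measured in
  standard y-up orientation. Single-pixel and collinear regions are
  degenerate-geometry errors.
* **Colour statistics.** Population moments (divide by n) per channel;
  skewness `m3/m2^1.5` and excess kurtosis `m4/m2^2 - 3` are defined as 0
  for zero-variance regions; integrated density is pixel count × mean.
* **View pairing.** How dorsal and ventral regions correspond is not
  observable from one image, so the package defines it: the ventral
  layout is mirrored horizontally (a flipped tray), both region lists are
  sorted in reading order (row bands at half the median region height,
  then x), and the order-preserving assignment pairs them. Count
  mismatches are errors that name the unmatched regions; nothing is
  silently dropped.
* **Colour calibration** against a physical reference chart is out of
  scope; a per-image linear white-balance hook exists but defaults to the
  identity.

## The 68-feature schema

13 size/shape descriptors plus 7 colour statistics × 3 channels = 34 per
view, × 2 views = 68. The canonical order is `feature_manifest()`:
dorsal shape, dorsal colour (stat-major within channel), then ventral.
Every named size, shape and colour variable of the measurement suite is
included; the schema lives in one place and pairing asserts against it.

## Data preparation

Species with 30 or fewer observations are moved to a *rare* partition —
not enough data to train on, but used later as novel species. Splits are
simple random 70:30, repeated 10 times by default, deliberately
non-stratified (so per-repeat class counts vary, as they do in practice);
a species dropping out of a training split is recorded as a warning.
Standardization (center, scale) is fit on the training rows only and
applied to both partitions; fitting on the pooled split is available as
`fit_on = "combined"` for protocols that standardized before splitting,
but train-only is the default because it avoids information leaking from
test rows into the transform. Zero-variance features pass through
centered, with a warning.

## Classifiers and tuning

All five algorithms emit a specimens × classes probability matrix whose
rows sum to 1, with a fixed ranking tie-break (descending probability,
then descending training-class frequency, then class name) so top-k sets
are deterministic.

* KNN: Euclidean distance on standardized features, neighbour-vote
  fractions as probabilities; k ∈ 1–25.
* LDA: `MASS::lda` posteriors; if the pooled covariance is singular the
  fit falls back to a ridge-regularized discriminant (λ = 10⁻³ of the
  mean diagonal), with a warning.
* Naive Bayes: `e1071::naiveBayes` parameters, with the posterior
  evaluated in log space — multiplying 68 Gaussian densities underflows
  double precision, log-sums do not.
* Random forest: `randomForest`, 500 trees, vote fractions; mtry ∈ 1–10.
* ANN: `nnet`, one hidden layer (logistic units, softmax outputs),
  weight decay 5·10⁻⁴, up to three seeded restarts on failure; hidden ∈
  1–25.

Gridded algorithms select the value maximizing top-1 accuracy. The
default mode is 5-fold cross-validation inside the training set; the
random forest uses out-of-bag error instead, its native equivalent at a
fifth of the cost. A `paper-fidelity` mode instead selects on a supplied
validation set — reproducing protocols that tune against the test set —
and flags the resulting model as leaking (`model$leakage`), because the
two modes answer different questions and should not be confused.

The most-common-species baseline predicts the majority training class
with probability 1 (lexicographically first on ties) and is always
included in experiments as the "by chance" reference.

## Evaluation protocols

* **Macro metrics.** Precision, recall and F1 are computed per class and
  averaged unweighted over the union of classes present in that repeat's
  truth or predictions; a class never predicted has precision 0, and F1
  is 0 where its denominator vanishes. Pooled results are means of
  per-repeat metrics, never metrics of pooled predictions.
* **Lifted top-k.** At a lifted rank, the k species-level predictions are
  lifted and de-duplicated in rank order before counting k — k *distinct
  taxa* is the meaningful contract, since two congeneric candidate
  species are one genus-level hypothesis.
* **Local pools.** Classes outside a specimen's site pool are removed and
  the remainder reranked by their original probabilities (renormalized).
  If every pooled class has probability 0, the pool is ranked by training
  frequency — a deterministic, documented fallback. Sites whose pool
  intersected with the model's classes is a single species are guaranteed
  perfect accuracy and are excluded from the pooled local statistic.
  Local accuracy is reported at the species rank only.
* **Novel species.** Rare-partition specimens are forced through the
  species-level model; a rank is measurable for a specimen only when its
  true label at that rank is shared with at least one training species.
  Accuracy is reported per rank alongside the measurable counts.
* **Confusion matrices.** Per-repeat matrices (rows predicted, columns
  actual) averaged cell-wise, with marginal totals and a
  column-percentage form.

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes,
with every ground truth known analytically:

* **Taxonomy**: configured taxon counts per rank, random parent
  assignment with every parent guaranteed a child. The emulation preset
  mirrors the reference survey's shape — 3,270 specimens, 64 species, 32
  genera, 19 tribes, 8 subfamilies, 18 sites (`study_shape()`).
* **Features**: per-species Gaussians in the 68 manifest dimensions whose
  means perform a random walk down the taxonomy (each taxon adds
  N(0, drift²) per coordinate to its parent's mean), so congeners are
  closer than cross-tribe species. The default drift of 0.2 against a
  within-species SD of 1 was chosen once so that the default regime
  resembles a real survey: high but imperfect species accuracy,
  near-perfect subfamily accuracy, and a visible local-pool gain. Drift 0
  gives the no-signal limit; large drift the Bayes-separable limit.
* **Abundances**: geometric decay (ratio 0.9 at full scale), integerized
  with a minimum of one specimen per species, putting roughly 60% of
  species at or below the 30-observation rare threshold — exercising the
  novel-species path.
* **Sites**: pool sizes drawn as a shifted binomial within 1–7 with mean
  3, species entering pools with probability proportional to abundance,
  a coverage fix-up guaranteeing every species at least one site, and
  specimens assigned uniformly among sites pooling their species.
* **Images**: specimens are rendered as rotated ellipses with per-channel
  Gaussian pixel noise on a near-white textured background, laid out on a
  grid, the ventral view mirrored. Area, axes and base colours are exact
  analytic truth. Ellipses are deliberately unrealistic: testability of
  the measurement chain outranks realism.

What the generator does **not** emulate: non-Gaussian or multimodal
within-species variation, touching or overlapping specimens, limb loss
and degradation, glare and shadow, pose variation, or correlated
measurement error between views. Tests passing on synthetic data
therefore validate the pipeline's mechanics and protocol logic, not
field-condition robustness.

All generation, splitting and training is seeded; identical configs and
seeds reproduce outputs byte for byte.

## Problem sizes used in the shipped runs

The test suite and the acceptance script run the *reduced* preset — 600
specimens, 12 species (11 groups, 8 genera, 6 subtribes, 5 tribes, 3
subfamilies), 12 sites, abundance ratio 0.78, 10 split repeats — with
moderate tuning grids (k ∈ 1–25, mtry ∈ {2,4,6,8}, hidden ∈ {3,6}, 200
trees, 3 CV folds, 300-epoch cap). These sizes are the package's chosen
desk-scale study conditions: large enough that every protocol (rare
filter, local pools, novel species, all five algorithms) is exercised
with stable orderings, small enough to iterate on. On this preset the
orderings reported for the full-scale reference dataset reproduce
qualitatively: LDA leads, accuracy rises monotonically with rank, local
pools raise species-level accuracy, and naive Bayes is strongest at
classifying novel species to genus.

## Known limitations

* The view-pairing strategy is an invention (the correspondence is not
  recoverable from single images); layouts that are not approximate
  mirrored grids may need manual pairing.
* Chain-code perimeter traces the outer boundary only; interior holes do
  not contribute (rare for beetle silhouettes, but a known difference
  from hole-aware conventions).
* Bounding-box width/height are axis-aligned, not rotated extents.
* On zero-signal data with strongly skewed classes, finite-k vote
  classifiers sit measurably *below* the majority-class baseline; the
  near-baseline sanity property is only expected under roughly balanced
  classes.
* The iNaturalist comparison, physical camera calibration, and
  significance testing between algorithms are out of scope.
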