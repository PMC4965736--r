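---
title: "Weighted similarity retrieval of pulmonary nodules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted similarity retrieval of pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleCBIR)
```

## The problem

Content-based image retrieval (CBIR) supports the reading of a pulmonary
nodule on CT by showing the radiologist previously diagnosed nodules that
look like the one under review. Two questions decide whether such a system
is useful: *which attributes* describe a nodule, and *how to weigh them*
when measuring similarity. This package implements a complete pipeline for
both: volumetric texture and margin-sharpness attribute extraction, a
weighted Euclidean similarity metric, and an automatic attribute-weighting
procedure that learns, from retrieval behavior alone, which attributes are
locally homogeneous among similar nodules and should therefore dominate
the metric.

Nodules carry an ordinal malignancy likelihood rating of 1–5 (LIDC-IDRI
convention); rating 3 (indeterminate) is excluded everywhere, ratings 1–2
are grouped *benign* and 4–5 *malignant* for evaluation.

## Texture attributes (36)

Texture is described by second-order statistics of gray-level
co-occurrence matrices (GLCM). For a quantized volume the matrix
$C(i,j)$ holds the probability of observing gray levels $i$ and $j$ at a
fixed spatial displacement. Nine statistics — energy, entropy, inverse
difference moment, inertia, variance, cluster shade, cluster prominence,
correlation and homogeneity — are computed for the four in-plane
orientations $0°, 45°, 90°, 135°$ at distance $d = 1$, giving a
36-dimension vector.

Design choices the data format does not pin down:

* **Quantization.** CT intensities are binned linearly over the masked
  voxel range into 64 levels by default. 64 keeps co-occurrence matrices
  of small nodules dense enough to carry signal while preserving contrast
  structure; the bin edges are half-open so the midpoint of a two-level
  quantization falls in the lower bin.
* **The third dimension.** The volumetric extension studies between-slice
  joint probabilities. With one matrix per between-slice direction the
  attribute count would exceed 9 × 4 = 36, so the between-slice pairs
  (the in-plane offset applied across adjacent slices, and the purely
  axial neighbor) are *folded into* each orientation's matrix. A
  `pairMode = "inplane"` switch restricts counting to within-slice pairs.
* **Symmetric counting and normalization.** Pairs are counted in both
  directions and normalized to probabilities — standard GLCM practice.
  Symmetry makes $\mu_x = \mu_y$ and $\sigma_x = \sigma_y$.
* **Entropy base.** Base-2 logarithm (bits); any other base is a monotone
  rescale. Cells with $C(i,j) = 0$ contribute zero.
* **Variance mean.** The variance statistic uses the row-marginal mean
  $\mu_x$; with a symmetric matrix the choice between $\mu_x$ and
  $\mu_y$ is immaterial.
* **Correlation convention.** The form implemented by default
  (`"printed"`) is $-\sum_{i,j}(i-\mu_x)(j-\mu_y)C(i,j) /
  \sqrt{\sigma_x\sigma_y}$ where $\sigma_x, \sigma_y$ are the marginal
  *variances* — so the denominator equals the product of marginal
  standard deviations and the statistic is the negative of the standard
  product-moment GLCM correlation. `correlationConvention = "haralick"`
  drops the leading minus. When $\sigma_x\sigma_y = 0$ (single-level
  matrix) correlation is defined as 0. As long as one convention is used
  consistently, retrieval is unaffected: z-score normalization makes the
  sign choice invisible to the metric.
* **Mask handling.** Only voxel pairs with both ends inside the
  segmentation mask are counted, so background never contaminates the
  statistics.

```{r texture-example}
ph <- generatePhantom(seed = 1)
gv <- quantizeVolume(ph$volume, ph$mask, levels = 64)
round(haralickStats(buildCOM(gv, orientation = 0)), 4)
```

## Margin-sharpness attributes (12)

Malignant nodules tend to infiltrate neighboring tissue, so how abruptly
intensity changes across the lesion boundary is diagnostic. The analysis
follows five stages per annotated slice:

1. **Control points.** Twenty points, spaced $\lfloor p/20 \rfloor$
   boundary pixels apart along the annotated contour of $p$ pixels,
   starting at the first marked point. Contours with $p < 20$ contribute
   every pixel, with a warning.
2. **Normal lines.** At each control point a digital segment perpendicular
   to the local tangent (central difference over contour neighbors at
   offset ±2), extending 6 pixels outward and 6 inward. The line length is
   a declared default, not a data-derived fact; it is configurable.
3. **Lung mask.** Pixels below an intensity threshold (Otsu's method by
   default, or a configured absolute value for calibrated CT) form the
   lung field; enclosed holes are filled; the result is dilated by a
   2-pixel disk. Hole filling is essential: a bright nodule inside the
   dark lung field is a hole in the thresholded mask, and without filling
   every normal-line pixel deeper inside the nodule than the dilation rim
   would be discarded.
4. **Clipping.** Segment pixels outside the mask (chest wall, mediastinum)
   are removed; segments left with fewer than two pixels are dropped.
   For juxtapleural nodules this is what keeps wall intensities out of
   the statistics.
5. **Pooling and statistics.** All surviving pixel intensities, across all
   slices, are pooled into a single ascending array $a_1 \le \dots \le
   a_n$, and twelve statistics are computed: difference of the two ends,
   sum, sum of squares, sum of logs, arithmetic and geometric means,
   population and sample variance, standard deviation, kurtosis, skewness
   and the second central moment.

Three conventions deserve note. The array is *always sorted ascending*;
for a bright nodule in a dark lung field the first entry is then an
outside-lung intensity and the last an inside-nodule one, so the
difference of ends measures the pooled intensity range. The shape
statistics divide central moments (1/n normalization) by powers of the
*sample* standard deviation, which makes the second central moment
identically $(n-1)/n$ — a deliberate, exact consequence of the printed
formulas that the tests assert. Logs and the geometric mean are taken on
raw stored (unsigned) gray values; if any value is non-positive, a +1
offset is applied to the whole array for those two statistics only.
Zero-dispersion arrays get skewness, kurtosis and second central moment 0
by convention.

## Normalization, similarity and splits

Attributes live on incommensurate scales, so each is z-scored,
$Z = (X - \bar{x})/\sigma$, with the population SD by default
(configurable to sample SD). The model is fit **on the training database
only** and applied out-of-sample to the evaluation and validation
databases, avoiding leakage; whether to normalize before or after
splitting was an open choice and this is the conservative one.

Similarity is the weighted Euclidean distance
$d(\vec{x}, \vec{y}) = \sqrt{\sum_f w_f (x_f - y_f)^2}$ with
non-negative weights. For fixed $w$ it satisfies symmetry,
non-negativity and the triangle inequality; a zero weight makes the
metric ignore that attribute. Retrieval is exact brute force (the
databases are small); ties are broken by ascending nodule id so rankings
are reproducible, and a query drawn from the database is excluded from
its own results.

The database is split per class into training / evaluation / validation
subsets — 65/65/30 nodules per malignancy class at full scale
(260/260/120 over four classes), reduced to 20/20/10 in the synthetic
benchmark so the complete learning loop runs in seconds.

## The weight-learning cycle

Weights start uniform, $w_f = 1/a$, and two stages alternate:

* **Evaluation stage.** Every evaluation nodule serves once as the query
  (leave-one-out); the top $n$ retrieved nodules are mapped to relevance
  rewards and scored with the exponentially discounted gain
  $v = \sum_{i=1}^{n} \gamma^i s_i$, the exponent starting at 1 so the
  best-placed results — the ones a reader actually inspects — dominate.
  The stage value is the *mean* gain over queries (the aggregation was an
  open choice; the mean keeps $v$ comparable across database sizes). The
  reward $s_i$ depends on the query's rating: for a malignant-side query
  (4 or 5), retrieved 5 → 4, 4 → 2, 2 or 1 → 0; for a benign-side query
  (1 or 2), retrieved 1 → 4, 2 → 2, 4 or 5 → 0. Irrelevant nodules earn
  nothing rather than a penalty.
* **Training stage.** For each training nodule (leave-one-out), the $n$
  nearest neighbors under the running weights form a matrix
  $R_{n \times a}$; each attribute column is projected out and its
  *inverse sample standard deviation* becomes the attribute's raw weight
  — attributes homogeneous among retrieved neighbors are good local
  indicators, dispersed ones are not. Raw weights are normalized to unit
  sum, and the memory is updated online after every query:
  $W^* = W + \alpha\,(W_{\text{current}} - W)$.

The best-scoring weights are tracked across cycles and the process stops
after `patience` cycles (default 100) without improvement, or at a hard
`maxCycles` cap (default 500; $v$ takes finitely many values, so
termination does not depend on the cap in practice).

Two ambiguities were resolved as package design choices:

* **Update direction.** Written with the difference $W - W_{\text{current}}$,
  the update moves the memory *away* from what the current iteration
  learned, which contradicts the stated role of $\alpha$ as a learning
  rate. The default is therefore the convergent form
  $W + \alpha(W_{\text{current}} - W)$; `updateSign = "printed"` restores
  the other sign for comparison. Updates are clipped at zero and
  renormalized, keeping every weight vector non-negative with unit sum.
* **Online vs batch.** $W_{\text{current}}$ is folded into the memory
  after every query rather than averaged over the pass, matching the
  description of per-iteration adjustment.

Degenerate dispersion is handled explicitly: a constant attribute column
has its SD floored at $10^{-6}$, and no single normalized weight may
exceed 0.99 (excess mass is redistributed proportionally), so one
constant column cannot collapse the whole vector.

Reference parameters are $n = 15$, $\alpha = 0.3$, $\gamma = 0.8$; the
surrounding grid $n \in \{10, 15, 20\}$, $\alpha \in \{0.2, 0.3, 0.4\}$,
$\gamma \in \{0.7, 0.8, 0.9\}$ is exposed through the command-line
`learn --grid` mode.

```{r learning-example}
bm <- generateBenchmark(seed = 1)
cfg <- trainingConfig(n = 15, alpha = 0.3, gamma = 0.8, patience = 20)
run <- runCycle(trainTable(bm$split), evalTable(bm$split), cfg)
round(run$WBest, 3)
```

## Evaluation

Retrieval quality is reported as interpolated precision at recall 25 %,
50 % and 75 % and as Precision($n$), separately for benign and malignant
queries, relevance being *same binary group as the query* (distinct from
the 4/2/0 reward ladder, which is used only inside learning). The
interpolation at recall level $r$ takes the maximum precision at any
recall $\ge r$ — the standard convention, adopted because none is
specified by the reporting format.

```{r eval-example}
vd <- validTable(bm$split)
round(evaluationReport(vd, run$WBest, n = 15), 3)
```

## What the synthetic generators emulate — and what they do not

`generateFeatureTable()` encodes exactly the premise the learning method
relies on: nodules of the same class have similar vectors on
*informative* attributes (within-class SD 0.2, class means 2.0 apart and
ordered along the malignancy scale so moderately relevant neighbors are
genuinely nearer than irrelevant ones), while *noise* attributes have SD
2.0 and no class structure. The benchmark uses 8 attributes of which 2
are informative, 4 classes, and 20/20/10 nodules per class per subset.

`generatePhantom()` builds an ellipsoidal lesion with a sigmoid radial
intensity profile of controllable edge width, additive Gaussian noise,
per-slice boundary contours drawn just outside the lesion, and an
optional bright wall plane for the juxtapleural mask-clipping case.

Passing tests on these generators show that the implementation does what
the formulas say and that the learning loop recovers a planted
low-dispersion structure. They do **not** show clinical performance:
real CT nodules have correlated attributes, heterogeneous textures,
annotation variability and class imbalance that the generators do not
model, so precision figures obtained on the benchmark are desk-scale
properties of the algorithm, not estimates of performance on patient
data.

## Problem sizes and numerical conventions

The test-suite and acceptance runs use volumes up to 8×8×4 voxels for
exhaustive co-occurrence checks (50 random volumes), 40×40×7 phantoms for
end-to-end extraction, and ten seeded benchmark replicates
(80/80/40-nodule splits, patience 20) for the learning-loop properties —
sizes chosen so a complete run takes well under a minute of compute per
module while still exercising every code path. Other conventions:
probability conservation of every co-occurrence matrix is asserted to
1e-12; texture statistics agree with a literal transcription of their
formulas to 1e-10; weight vectors are renormalized after every update;
and all generators are pure functions of their seed, making every
pipeline stage bit-reproducible.

## Known limitations

* Contours are consumed in a simple JSON format; a converter from
  LIDC-style XML is a documented extension point, not included.
* No sub-pixel interpolation along normal lines; intensities are read at
  rasterized pixel centers.
* The reward policy and benign/malignant grouping are fixed to the 1–5
  rating scheme; multiclass evaluation and malignancy-correlated
  weighting are out of scope.
* Retrieval is exact brute force; no indexing structures are provided or
  needed at these database sizes.
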