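#' @import methods
NULL

#' Quantized gray-level volume with a segmentation mask
#'
#' Container for a segmented 3D lesion: an array of integer gray levels in
#' `[0, levels - 1]`, a logical mask of the same shape marking nodule voxels,
#' and the axis that indexes slices (always the third axis here; slices are
#' `voxels[, , s]`).
#'
#' @slot voxels 3D integer array of quantized gray levels.
#' @slot levels Number of quantization bins `L`; all voxel values lie in
#'   `[0, L - 1]`.
#' @slot mask Logical array, same shape as `voxels`, `TRUE` for nodule voxels.
#' @slot sliceAxis Axis indexing slices (fixed at 3).
#'
#' @seealso [quantizeVolume()] to construct one from raw intensities,
#'   [buildCOM()], [textureVector()].
#' @export
setClass("GrayVolume",
  representation(voxels = "array", levels = "integer", mask = "array",
                 sliceAxis = "integer"))

setValidity("GrayVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3D array")
  if (!identical(dim(object@voxels), dim(object@mask)))
    msg <- c(msg, "'mask' must have the same shape as 'voxels'")
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  if (length(object@levels) != 1L || object@levels < 2L)
    msg <- c(msg, "'levels' must be a single integer >= 2")
  v <- object@voxels
  if (any(v < 0L) || any(v > object@levels - 1L))
    msg <- c(msg, "voxel values must lie in [0, levels - 1]")
  if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one voxel")
  if (!identical(object@sliceAxis, 3L))
    msg <- c(msg, "'sliceAxis' must be 3 (slices are voxels[, , s])")
  if (length(msg)) msg else TRUE
})

#' Construct a GrayVolume
#'
#' @param voxels 3D array of integer gray levels in `[0, levels - 1]`.
#' @param levels Number of gray levels `L`.
#' @param mask Logical array of the same shape; defaults to all `TRUE`.
#' @return A [GrayVolume-class] object.
#' @export
GrayVolume <- function(voxels, levels, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(voxels))
  storage.mode(voxels) <- "integer"
  new("GrayVolume", voxels = voxels, levels = as.integer(levels),
      mask = mask, sliceAxis = 3L)
}

setMethod("show", "GrayVolume", function(object) {
  d <- dim(object@voxels)
  cat("GrayVolume:", paste(d, collapse = " x "),
      "|", object@levels, "gray levels |",
      sum(object@mask), "masked voxels\n")
})

#' Normalized gray-level co-occurrence matrix
#'
#' Joint probability `C(i, j)` of gray-level pairs at a fixed spatial offset,
#' accumulated over a [GrayVolume-class] for one in-plane orientation and
#' pixel distance. Integer pair counts prior to normalization are retained in
#' `counts` so exact count-level checks remain possible.
#'
#' @slot probs `L x L` matrix of pair probabilities `C(i, j)`; entries are non-negative and
#'   sum to 1.
#' @slot counts `L x L` matrix of symmetric integer pair counts.
#' @slot orientation In-plane orientation in degrees (0, 45, 90 or 135).
#' @slot distance Pixel offset distance `d`.
#' @slot pairMode `"full3d"` (in-plane plus between-slice pairs) or
#'   `"inplane"`.
#'
#' @seealso [buildCOM()], [haralickStats()], [comMarginals()].
#' @export
setClass("CooccurrenceMatrix",
  representation(probs = "matrix", counts = "matrix", orientation = "numeric",
                 distance = "integer", pairMode = "character"))

setValidity("CooccurrenceMatrix", function(object) {
  msg <- character()
  if (nrow(object@probs) != ncol(object@probs))
    msg <- c(msg, "'C' must be square")
  if (any(object@probs < 0))
    msg <- c(msg, "'C' entries must be non-negative")
  if (abs(sum(object@probs) - 1) > 1e-9)
    msg <- c(msg, "'C' must sum to 1")
  if (!object@orientation %in% c(0, 45, 90, 135))
    msg <- c(msg, "orientation must be one of 0, 45, 90, 135 degrees")
  if (object@distance < 1L)
    msg <- c(msg, "distance must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat("CooccurrenceMatrix:", nrow(object@probs), "x", ncol(object@probs),
      "| orientation", object@orientation, "deg | d =", object@distance,
      "|", object@pairMode, "pairs |", sum(object@counts), "pair counts\n")
})

#' Per-nodule feature table
#'
#' Rows are nodules, columns are attributes; each nodule carries an integer
#' malignancy likelihood rating in `{1, 2, 4, 5}` (rating 3, indeterminate,
#' is excluded upstream). `vectorKind` records which attribute set the
#' columns hold: `"TA36"` (36 texture attributes), `"MSA12"` (12
#' margin-sharpness attributes), `"InV48"` (their concatenation) or
#' `"custom"` for synthetic tables of any width.
#'
#' @slot features Numeric matrix, rownames are nodule ids.
#' @slot malignancy Integer vector in `{1, 2, 4, 5}`, one per row.
#' @slot vectorKind One of `"TA36"`, `"MSA12"`, `"InV48"`, `"custom"`.
#'
#' @seealso [FeatureTable()], [featureMatrix()], [readFeatureTable()].
#' @export
setClass("FeatureTable",
  representation(features = "matrix", malignancy = "integer",
                 vectorKind = "character"))

.kindWidth <- c(TA36 = 36L, MSA12 = 12L, InV48 = 48L)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (is.null(rownames(object@features)))
    msg <- c(msg, "'features' must have nodule ids as rownames")
  if (anyDuplicated(rownames(object@features)))
    msg <- c(msg, "nodule ids must be unique")
  if (length(object@malignancy) != nrow(object@features))
    msg <- c(msg, "one malignancy rating per row is required")
  if (!all(object@malignancy %in% c(1L, 2L, 4L, 5L)))
    msg <- c(msg, "malignancy ratings must be in {1, 2, 4, 5}")
  if (anyNA(object@features))
    msg <- c(msg, "feature values must not contain NA")
  k <- object@vectorKind
  if (!k %in% c(names(.kindWidth), "custom"))
    msg <- c(msg, "vectorKind must be TA36, MSA12, InV48 or custom")
  if (k %in% names(.kindWidth) && ncol(object@features) != .kindWidth[[k]])
    msg <- c(msg, sprintf("vectorKind %s requires %d attributes, found %d",
                          k, .kindWidth[[k]], ncol(object@features)))
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param features Numeric matrix (rows = nodules, columns = attributes).
#' @param malignancy Integer malignancy ratings in `{1, 2, 4, 5}`.
#' @param vectorKind Attribute-set label; see [FeatureTable-class].
#' @param noduleId Optional nodule ids; default taken from rownames, or
#'   generated as `N0001, ...`.
#' @return A [FeatureTable-class] object.
#' @export
FeatureTable <- function(features, malignancy, vectorKind = "custom",
                         noduleId = NULL) {
  features <- as.matrix(features)
  if (!is.null(noduleId)) rownames(features) <- noduleId
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("N%04d", seq_len(nrow(features)))
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("attr%02d", seq_len(ncol(features)))
  new("FeatureTable", features = features,
      malignancy = as.integer(malignancy), vectorKind = vectorKind)
}

setMethod("show", "FeatureTable", function(object) {
  cat("FeatureTable (", object@vectorKind, "): ",
      nrow(object@features), " nodules x ", ncol(object@features),
      " attributes\n", sep = "")
  tab <- table(object@malignancy)
  cat("  malignancy:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
})

#' Per-attribute z-score normalization model
#'
#' Stores the per-attribute mean and standard deviation estimated from a
#' training table, so that evaluation and validation tables can be
#' transformed out-of-sample.
#'
#' @slot center Named numeric vector of attribute means.
#' @slot scale Named numeric vector of attribute standard deviations
#'   (floored at `1e-12` for constant attributes).
#' @slot type `"population"` or `"sample"` standard deviation.
#'
#' @seealso [fitZscore()], [applyZscore()].
#' @export
setClass("NormalizationModel",
  representation(center = "numeric", scale = "numeric", type = "character"))

setValidity("NormalizationModel", function(object) {
  msg <- character()
  if (length(object@center) != length(object@scale))
    msg <- c(msg, "'center' and 'scale' must have equal length")
  if (any(object@scale < 0))
    msg <- c(msg, "'scale' must be non-negative")
  if (!object@type %in% c("population", "sample"))
    msg <- c(msg, "type must be 'population' or 'sample'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NormalizationModel", function(object) {
  cat("NormalizationModel (", object@type, " SD) for ",
      length(object@center), " attributes\n", sep = "")
})

#' Three-way train / evaluation / validation split
#'
#' Disjoint, class-balanced partition of a [FeatureTable-class] into the
#' training, evaluation and validation databases used by the weight-learning
#' cycle. The manifest records the nodule ids per subset, the per-class
#' counts and the seed, so the split is reproducible.
#'
#' @slot train,eval,valid [FeatureTable-class] subsets.
#' @slot manifest List with `seed`, `counts` and per-subset nodule ids.
#'
#' @seealso [makeSplit()], [generateBenchmark()].
#' @export
setClass("DatabaseSplit",
  representation(train = "FeatureTable", eval = "FeatureTable",
                 valid = "FeatureTable", manifest = "list"))

setValidity("DatabaseSplit", function(object) {
  ids <- c(rownames(object@train@features), rownames(object@eval@features),
           rownames(object@valid@features))
  if (anyDuplicated(ids)) "subsets must hold disjoint nodule ids" else TRUE
})

setMethod("show", "DatabaseSplit", function(object) {
  cat("DatabaseSplit: train", nrow(object@train@features),
      "| eval", nrow(object@eval@features),
      "| valid", nrow(object@valid@features), "nodules\n")
})

#' Ordered retrieval result for one query nodule
#'
#' The `n` most similar stored nodules for a query, ordered by ascending
#' weighted Euclidean distance (ties broken by nodule id). `R` is the
#' `n x a` matrix of attribute values of the retrieved nodules, in retrieval
#' order, used by the inverse-SD weight update.
#'
#' @slot queryId Query nodule id (or `"<query>"` for an ad-hoc vector).
#' @slot queryMalignancy Malignancy rating of the query (`NA` for ad-hoc).
#' @slot ranking `data.frame` with columns `rank`, `noduleId`, `malignancy`,
#'   `distance`, distances non-decreasing.
#' @slot R Numeric matrix of retrieved attribute values, one row per rank.
#'
#' @seealso [retrieveSimilar()], [isdWeights()].
#' @export
setClass("RetrievalRanking",
  representation(queryId = "character", queryMalignancy = "integer",
                 ranking = "data.frame", R = "matrix"))

setValidity("RetrievalRanking", function(object) {
  msg <- character()
  d <- object@ranking$distance
  if (is.unsorted(d)) msg <- c(msg, "distances must be non-decreasing")
  if (nrow(object@ranking) != nrow(object@R))
    msg <- c(msg, "'R' must have one row per retrieved nodule")
  if (object@queryId %in% object@ranking$noduleId)
    msg <- c(msg, "the query must not appear among its own results")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RetrievalRanking", function(object) {
  cat("RetrievalRanking: query", object@queryId, "->",
      nrow(object@ranking), "nodules, distances in [",
      format(min(object@ranking$distance), digits = 4), ",",
      format(max(object@ranking$distance), digits = 4), "]\n")
})
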