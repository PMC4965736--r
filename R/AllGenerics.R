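#' Accessors for package classes
#'
#' Small accessor generics: `voxelData()`, `noduleMask()` and `grayLevels()`
#' read the slots of a [GrayVolume-class]; `comMatrix()` and `comCounts()`
#' the probability and count matrices of a [CooccurrenceMatrix-class];
#' `featureMatrix()`, `noduleIds()`, `malignancy()` and `vectorKind()` the
#' contents of a [FeatureTable-class]; `rankingTable()` and
#' `retrievedMatrix()` the ordered results of a [RetrievalRanking-class];
#' `trainTable()`, `evalTable()` and `validTable()` the subsets of a
#' [DatabaseSplit-class].
#'
#' @param x Object to access.
#' @return The slot contents (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("noduleMask", function(x) standardGeneric("noduleMask"))
#' @rdname accessors
#' @export
setGeneric("grayLevels", function(x) standardGeneric("grayLevels"))
#' @rdname accessors
#' @export
setGeneric("comMatrix", function(x) standardGeneric("comMatrix"))
#' @rdname accessors
#' @export
setGeneric("comCounts", function(x) standardGeneric("comCounts"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("noduleIds", function(x) standardGeneric("noduleIds"))
#' @rdname accessors
#' @export
setGeneric("malignancy", function(x) standardGeneric("malignancy"))
#' @rdname accessors
#' @export
setGeneric("vectorKind", function(x) standardGeneric("vectorKind"))
#' @rdname accessors
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))
#' @rdname accessors
#' @export
setGeneric("retrievedMatrix", function(x) standardGeneric("retrievedMatrix"))
#' @rdname accessors
#' @export
setGeneric("trainTable", function(x) standardGeneric("trainTable"))
#' @rdname accessors
#' @export
setGeneric("evalTable", function(x) standardGeneric("evalTable"))
#' @rdname accessors
#' @export
setGeneric("validTable", function(x) standardGeneric("validTable"))

#' @rdname accessors
#' @export
setMethod("voxelData", "GrayVolume", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("noduleMask", "GrayVolume", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("grayLevels", "GrayVolume", function(x) x@levels)
#' @rdname accessors
#' @export
setMethod("comMatrix", "CooccurrenceMatrix", function(x) x@probs)
#' @rdname accessors
#' @export
setMethod("comCounts", "CooccurrenceMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("noduleIds", "FeatureTable", function(x) rownames(x@features))
#' @rdname accessors
#' @export
setMethod("malignancy", "FeatureTable", function(x) x@malignancy)
#' @rdname accessors
#' @export
setMethod("vectorKind", "FeatureTable", function(x) x@vectorKind)
#' @rdname accessors
#' @export
setMethod("rankingTable", "RetrievalRanking", function(x) x@ranking)
#' @rdname accessors
#' @export
setMethod("retrievedMatrix", "RetrievalRanking", function(x) x@R)
#' @rdname accessors
#' @export
setMethod("trainTable", "DatabaseSplit", function(x) x@train)
#' @rdname accessors
#' @export
setMethod("evalTable", "DatabaseSplit", function(x) x@eval)
#' @rdname accessors
#' @export
setMethod("validTable", "DatabaseSplit", function(x) x@valid)

#' Number of nodules in a FeatureTable
#' @param x A [FeatureTable-class].
#' @return Integer row count.
#' @export
setMethod("length", "FeatureTable", function(x) nrow(x@features))

#' Subset a FeatureTable by row
#' @param x A [FeatureTable-class].
#' @param i Row index (integer, logical or nodule id).
#' @param j,...,drop Ignored.
#' @return A [FeatureTable-class] with the selected nodules.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, rownames(x@features))
  new("FeatureTable", features = x@features[i, , drop = FALSE],
      malignancy = x@malignancy[i], vectorKind = x@vectorKind)
})
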