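#' Concatenate texture and margin vectors into an integrated vector
#'
#' Produces the 48-attribute integrated vector: the 36 texture attributes
#' first, then the 12 margin-sharpness attributes.
#'
#' @param ta Numeric texture vector of length 36 (see [textureVector()]).
#' @param msa Numeric margin vector of length 12 (see [marginVector()]).
#' @return Named numeric vector of length 48.
#' @export
concatVectors <- function(ta, msa) {
  if (length(ta) != 36L)
    stop("texture vector must have 36 attributes, found ", length(ta))
  if (length(msa) != 12L)
    stop("margin vector must have 12 attributes, found ", length(msa))
  c(ta, msa)
}

#' Fit a z-score normalization model
#'
#' Estimates per-attribute mean and standard deviation from a training
#' table. The default is the population SD (divisor `n`); `type = "sample"`
#' uses the `n - 1` divisor. Constant attributes get their SD floored at
#' `1e-12` with a warning, so their normalized values are 0.
#'
#' @param table A [FeatureTable-class] with at least 2 rows.
#' @param type `"population"` (default) or `"sample"`.
#' @return A [NormalizationModel-class].
#' @export
fitZscore <- function(table, type = c("population", "sample")) {
  type <- match.arg(type)
  X <- featureMatrix(table)
  if (nrow(X) < 2L) stop("need >= 2 rows to fit a normalization model")
  ctr <- colMeans(X)
  dev <- sweep(X, 2, ctr)
  n <- nrow(X)
  sd2 <- colSums(dev^2) / if (type == "population") n else n - 1
  sc <- sqrt(sd2)
  if (any(sc < 1e-12)) {
    warning("constant attribute(s): SD floored at 1e-12: ",
            paste(colnames(X)[sc < 1e-12], collapse = ", "))
    sc <- pmax(sc, 1e-12)
  }
  new("NormalizationModel", center = ctr, scale = sc, type = type)
}

#' Apply a z-score normalization model to a feature table
#'
#' Transforms every attribute to `(X - mean) / SD` using the model's
#' training-set statistics; applied out-of-sample, the transformed columns
#' need not have mean 0.
#'
#' @param model A [NormalizationModel-class] from [fitZscore()].
#' @param table A [FeatureTable-class] with matching attribute names.
#' @return A normalized [FeatureTable-class].
#' @export
applyZscore <- function(model, table) {
  X <- featureMatrix(table)
  if (!identical(colnames(X), names(model@center)))
    stop("attribute names of model and table do not match")
  Z <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  new("FeatureTable", features = Z, malignancy = table@malignancy,
      vectorKind = table@vectorKind)
}

#' Split a feature table into train / evaluation / validation databases
#'
#' Seeded uniform sampling without replacement, per malignancy class, into
#' three disjoint class-balanced subsets. At full scale the counts are
#' 65/65/30 per class (260/260/120 nodules over four classes); reduced
#' counts keep synthetic runs fast.
#'
#' @param table A [FeatureTable-class]; malignancy-3 nodules must already be
#'   absent (they never enter a [FeatureTable-class]).
#' @param counts Named integer vector `c(train=, eval=, valid=)` per class.
#' @param seed Integer seed for the sampling.
#' @return A [DatabaseSplit-class].
#' @export
makeSplit <- function(table, counts = c(train = 65L, eval = 65L, valid = 30L),
                      seed = 1L) {
  stopifnot(all(c("train", "eval", "valid") %in% names(counts)))
  need <- sum(counts)
  mal <- malignancy(table)
  ids <- noduleIds(table)
  set.seed(as.integer(seed))
  pick <- list(train = character(), eval = character(), valid = character())
  for (cl in sort(unique(mal))) {
    clIds <- ids[mal == cl]
    if (length(clIds) < need)
      stop(sprintf("class %d has %d nodules; %d required", cl,
                   length(clIds), need))
    perm <- sample(clIds, need)
    pick$train <- c(pick$train, perm[seq_len(counts[["train"]])])
    pick$eval <- c(pick$eval,
                   perm[counts[["train"]] + seq_len(counts[["eval"]])])
    pick$valid <- c(pick$valid,
                    perm[counts[["train"]] + counts[["eval"]] +
                           seq_len(counts[["valid"]])])
  }
  new("DatabaseSplit",
      train = table[pick$train], eval = table[pick$eval],
      valid = table[pick$valid],
      manifest = list(seed = as.integer(seed), counts = as.list(counts),
                      train = pick$train, eval = pick$eval,
                      valid = pick$valid))
}

#' Read / write feature tables as CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `noduleId,malignancy,<attr1>,...` and deterministic column order; values
#' are written at 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param table A [FeatureTable-class].
#' @param path CSV file path.
#' @param vectorKind Attribute-set label to stamp on the table read back.
#' @return `readFeatureTable` returns a [FeatureTable-class];
#'   `writeFeatureTable` returns `path` invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  X <- featureMatrix(table)
  num <- matrix(sprintf("%.17g", X), nrow(X), ncol(X),
                dimnames = dimnames(X))
  df <- data.frame(noduleId = rownames(X), malignancy = malignancy(table),
                   num, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path, vectorKind = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(X) <- df$noduleId
  if (is.null(vectorKind)) {
    w <- ncol(X)
    vectorKind <- if (w == 36L) "TA36" else if (w == 12L) "MSA12"
      else if (w == 48L) "InV48" else "custom"
  }
  new("FeatureTable", features = X, malignancy = as.integer(df$malignancy),
      vectorKind = vectorKind)
}

#' Write a split manifest as JSON
#'
#' Records the nodule ids per subset, per-class counts and seed of a
#' [DatabaseSplit-class].
#'
#' @param split A [DatabaseSplit-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeSplitManifest <- function(split, path) {
  jsonlite::write_json(split@manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write nodule contour annotations as JSON
#'
#' One JSON file per nodule: `{nodule_id, malignancy, slices:
#' [{slice_index, points: [[row, col], ...]}]}` with 0-based coordinates,
#' points in boundary traversal order and the first point being the first
#' marked point. In memory, slice indices and coordinates are 1-based.
#'
#' @param contours List with `noduleId`, `malignancy` and `slices` (each
#'   with 1-based `sliceIndex` and `points` matrix).
#' @param path JSON file path.
#' @return `readContours` returns the in-memory (1-based) contour list;
#'   `writeContours` returns `path` invisibly.
#' @export
writeContours <- function(contours, path) {
  out <- list(
    nodule_id = contours$noduleId,
    malignancy = if (isTRUE(is.na(contours$malignancy))) NULL
                 else contours$malignancy,
    slices = lapply(contours$slices, function(sl)
      list(slice_index = sl$sliceIndex - 1L,
           points = unname(sl$points - 1L))))
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeContours
#' @export
readContours <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(noduleId = raw$nodule_id,
       malignancy = if (length(raw$malignancy) != 1L) NA_integer_
                    else as.integer(raw$malignancy),
       slices = lapply(seq_len(nrow(raw$slices)), function(i) {
         pts <- raw$slices$points[[i]]
         list(sliceIndex = as.integer(raw$slices$slice_index[i]) + 1L,
              points = matrix(as.integer(pts), ncol = 2) + 1L)
       }))
}
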