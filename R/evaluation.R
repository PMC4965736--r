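#' Group malignancy ratings into benign / malignant
#'
#' Ratings 1 and 2 are grouped as benign, 4 and 5 as malignant; rating 3
#' (indeterminate) is never present and raises an error.
#'
#' @param m Integer vector of malignancy ratings.
#' @return Character vector of `"benign"` / `"malignant"`.
#' @export
malignancyGroup <- function(m) {
  if (any(!m %in% c(1L, 2L, 4L, 5L)))
    stop("malignancy ratings must be in {1, 2, 4, 5}")
  ifelse(m <= 2L, "benign", "malignant")
}

#' Retrieval precision and recall
#'
#' `retrievalPrecision` is the fraction of retrieved objects that are
#' relevant; `retrievalRecall` the fraction of relevant objects retrieved.
#'
#' @param relevantRetrieved Count of relevant objects among the retrieved.
#' @param totalRetrieved Total number of objects retrieved (>= 1).
#' @param totalRelevant Total number of relevant objects in the database
#'   (>= 1).
#' @return Fraction in `[0, 1]`.
#' @export
retrievalPrecision <- function(relevantRetrieved, totalRetrieved) {
  if (totalRetrieved < 1) stop("'totalRetrieved' must be >= 1")
  relevantRetrieved / totalRetrieved
}

#' @rdname retrievalPrecision
#' @export
retrievalRecall <- function(relevantRetrieved, totalRelevant) {
  if (totalRelevant < 1) stop("'totalRelevant' must be >= 1")
  relevantRetrieved / totalRelevant
}

## Full leave-one-out ranking relevance per query: list of logical vectors
## (relevant = same benign/malignant group as the query), in rank order.
.looRelevance <- function(db, w) {
  X <- featureMatrix(db)
  grp <- malignancyGroup(malignancy(db))
  N <- nrow(X)
  ids <- rownames(X)
  lapply(seq_len(N), function(q) {
    cand <- setdiff(seq_len(N), q)
    d <- .wedToAll(X[q, ], X[cand, , drop = FALSE], w)
    ord <- cand[order(d, ids[cand])]
    grp[ord] == grp[q]
  })
}

#' Interpolated precision-recall curve over leave-one-out retrieval
#'
#' Every nodule serves once as the query against all others; relevance is
#' sharing the query's benign/malignant group. For each query the full
#' ranking is scanned and the interpolated precision at each recall level
#' (the maximum precision at recall >= the level) is taken; results are
#' averaged separately over benign and over malignant queries.
#'
#' @param db A [FeatureTable-class] containing both groups.
#' @param w Non-negative attribute weight vector.
#' @param recallLevels Recall fractions to report (default 0.25, 0.50,
#'   0.75).
#' @return Matrix with rows `benign`, `malignant` and one column per recall
#'   level, entries in `[0, 1]`.
#' @export
prCurve <- function(db, w, recallLevels = c(0.25, 0.50, 0.75)) {
  grp <- malignancyGroup(malignancy(db))
  if (length(unique(grp)) < 2L)
    stop("precision-recall needs both benign and malignant nodules")
  rel <- .looRelevance(db, w)
  perQuery <- t(vapply(rel, function(r) {
    cumRel <- cumsum(r)
    prec <- cumRel / seq_along(r)
    rec <- cumRel / sum(r)
    vapply(recallLevels, function(lev) max(prec[rec >= lev]), numeric(1))
  }, numeric(length(recallLevels))))
  out <- rbind(benign = colMeans(perQuery[grp == "benign", , drop = FALSE]),
               malignant = colMeans(perQuery[grp == "malignant", ,
                                             drop = FALSE]))
  colnames(out) <- paste0("recall", recallLevels * 100)
  out
}

#' Mean precision among the first n retrieved nodules
#'
#' Precision(n): for each leave-one-out query, the fraction of the first
#' `n` retrieved nodules sharing the query's benign/malignant group,
#' averaged separately over benign and malignant queries.
#'
#' @param db A [FeatureTable-class] with more than `n` nodules.
#' @param w Non-negative attribute weight vector.
#' @param n Retrieval depth (default 30).
#' @return Named numeric vector `c(benign=, malignant=)`.
#' @export
precisionAtN <- function(db, w, n = 30L) {
  if (n >= length(db)) stop("'n' must be smaller than the database size")
  grp <- malignancyGroup(malignancy(db))
  rel <- .looRelevance(db, w)
  pn <- vapply(rel, function(r) mean(r[seq_len(n)]), numeric(1))
  c(benign = mean(pn[grp == "benign"]),
    malignant = mean(pn[grp == "malignant"]))
}

#' Precision-recall report for a weighted retrieval configuration
#'
#' Convenience wrapper combining [prCurve()] and [precisionAtN()] into one
#' data frame laid out per query group.
#'
#' @param db A [FeatureTable-class].
#' @param w Non-negative attribute weight vector.
#' @param n Depth for Precision(n); must be below the database size.
#' @param recallLevels Passed to [prCurve()].
#' @return `data.frame` with columns `group`, `recall25`... and
#'   `precisionAtN`.
#' @export
evaluationReport <- function(db, w, n = 30L,
                             recallLevels = c(0.25, 0.50, 0.75)) {
  pr <- prCurve(db, w, recallLevels)
  pn <- precisionAtN(db, w, n)
  data.frame(group = rownames(pr), pr, precisionAtN = pn[rownames(pr)],
             row.names = NULL, check.names = FALSE)
}
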