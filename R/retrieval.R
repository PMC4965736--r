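#' Weighted Euclidean distance
#'
#' `sqrt(sum(w * (x - y)^2))`. With non-negative weights this satisfies
#' symmetry, non-negativity and the triangle inequality; smaller values
#' mean more similar nodules, and a zero weight makes the distance ignore
#' that attribute entirely.
#'
#' @param x,y Numeric attribute vectors of equal length.
#' @param w Non-negative weight vector of the same length.
#' @return Single non-negative distance.
#' @examples
#' wed(c(0, 0), c(3, 4), c(1, 1))  # 5
#' @export
wed <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w))
    stop("'x', 'y' and 'w' must have equal length")
  if (any(w < 0)) stop("weights must be non-negative")
  sqrt(sum(w * (x - y)^2))
}

## Distances from one query vector to every row of X, vectorized.
.wedToAll <- function(q, X, w) {
  d2 <- sweep(X, 2, q)^2 %*% w
  sqrt(as.numeric(d2))
}

#' Retrieve the most similar nodules for a query
#'
#' Ranks the stored nodules by ascending weighted Euclidean distance to the
#' query and returns the `n` nearest. Ties are broken by ascending nodule
#' id so rankings are deterministic. When the query is given as a nodule id
#' present in the database it is excluded from its own results
#' (leave-one-out semantics).
#'
#' @param query Either a nodule id present in `database`, or a numeric
#'   attribute vector.
#' @param database A [FeatureTable-class].
#' @param w Non-negative weight vector, one entry per attribute.
#' @param n Number of nodules to retrieve (>= 1).
#' @return A [RetrievalRanking-class].
#' @export
retrieveSimilar <- function(query, database, w, n) {
  X <- featureMatrix(database)
  if (n < 1L) stop("'n' must be >= 1")
  if (any(w < 0)) stop("weights must be non-negative")
  if (length(w) != ncol(X))
    stop("weight vector length must match the attribute count")
  ids <- rownames(X)
  if (is.character(query) && length(query) == 1L) {
    qi <- match(query, ids)
    if (is.na(qi)) stop("query nodule id not found in the database")
    qv <- X[qi, ]
    qid <- query
    qmal <- malignancy(database)[qi]
    cand <- setdiff(seq_len(nrow(X)), qi)
  } else {
    qv <- as.numeric(query)
    if (length(qv) != ncol(X))
      stop("query vector length must match the attribute count")
    qid <- "<query>"
    qmal <- NA_integer_
    cand <- seq_len(nrow(X))
  }
  if (n > length(cand))
    stop("'n' exceeds the number of candidate nodules")
  d <- .wedToAll(qv, X[cand, , drop = FALSE], w)
  ord <- cand[order(d, ids[cand])][seq_len(n)]
  dOrd <- .wedToAll(qv, X[ord, , drop = FALSE], w)
  new("RetrievalRanking", queryId = qid, queryMalignancy = qmal,
      ranking = data.frame(rank = seq_len(n), noduleId = ids[ord],
                           malignancy = malignancy(database)[ord],
                           distance = dOrd),
      R = X[ord, , drop = FALSE])
}

#' Write a retrieval ranking as CSV
#'
#' Columns `rank,noduleId,malignancy,distance`, one row per retrieved
#' nodule.
#'
#' @param ranking A [RetrievalRanking-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeRanking <- function(ranking, path) {
  utils::write.csv(rankingTable(ranking), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
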