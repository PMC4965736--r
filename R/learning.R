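#' Relevance reward for a retrieved nodule
#'
#' Reward ladder used by the evaluation function. For a malignant-side
#' query (rating 4 or 5): retrieved rating 5 is highly relevant (reward 4),
#' 4 moderately relevant (2), and 1 or 2 irrelevant (0). For a benign-side
#' query (rating 1 or 2): retrieved 1 rewards 4, 2 rewards 2, and 4 or 5
#' reward 0. Irrelevant nodules receive no positive reward because they can
#' mislead the reading specialist.
#'
#' @param queryMalignancy Rating of the reference nodule (1, 2, 4 or 5).
#' @param retrievedMalignancy Ratings of retrieved nodules (vectorized).
#' @return Numeric rewards in `{4, 2, 0}`.
#' @export
rewardValue <- function(queryMalignancy, retrievedMalignancy) {
  ok <- c(1L, 2L, 4L, 5L)
  if (!queryMalignancy %in% ok || !all(retrievedMalignancy %in% ok))
    stop("malignancy ratings must be in {1, 2, 4, 5}")
  map <- if (queryMalignancy >= 4L)
    c(`1` = 0, `2` = 0, `4` = 2, `5` = 4)
  else
    c(`1` = 4, `2` = 2, `4` = 0, `5` = 0)
  unname(map[as.character(retrievedMalignancy)])
}

#' Exponentially discounted gain of a reward sequence
#'
#' `sum(gamma^i * s[i])` over ranks `i = 1..n` (the exponent starts at 1),
#' so rewards earned early in the ranking count more: with a large result
#' list the user attends mostly to the best-placed nodules.
#'
#' @param rewards Numeric reward sequence in rank order.
#' @param gamma Discount factor in `(0, 1]`.
#' @return Single numeric gain.
#' @examples
#' discountedGain(c(4, 2, 0), 0.8)  # 0.8*4 + 0.64*2 = 4.48
#' @export
discountedGain <- function(rewards, gamma) {
  if (gamma <= 0 || gamma > 1) stop("'gamma' must be in (0, 1]")
  if (!length(rewards)) return(0)
  sum(gamma^seq_along(rewards) * rewards)
}

#' Configuration for the weight-learning process
#'
#' Validated parameter bundle. Reference values `n = 15`, `alpha = 0.3`,
#' `gamma = 0.8`; the surrounding test grid uses `n` in `{10, 15, 20}`,
#' `alpha` in `{0.2, 0.3, 0.4}` and `gamma` in `{0.7, 0.8, 0.9}`.
#'
#' @param n Number of nodules retrieved per query (>= 1).
#' @param alpha Adjust factor in `(0, 1)`: how strongly each iteration's
#'   current weights move the learning memory.
#' @param gamma Discount factor in `(0, 1]` for [discountedGain()].
#' @param patience Cycles without improvement of the best evaluation value
#'   before stopping (default 100).
#' @param updateSign `"convergent"` (default) moves the memory towards the
#'   current weights, `W + alpha * (WCurrent - W)`; `"printed"` applies
#'   `W + alpha * (W - WCurrent)`.
#' @param maxCycles Hard cap on cycles (safety bound, default 500).
#' @param sdFloor Floor for a constant attribute's SD in [isdWeights()].
#' @param weightCap Maximum share any single normalized weight may take.
#' @return Validated list of class `trainingConfig`.
#' @export
trainingConfig <- function(n = 15L, alpha = 0.3, gamma = 0.8,
                           patience = 100L,
                           updateSign = c("convergent", "printed"),
                           maxCycles = 500L, sdFloor = 1e-6,
                           weightCap = 0.99) {
  updateSign <- match.arg(updateSign)
  if (n < 1L) stop("'n' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (gamma <= 0 || gamma > 1) stop("'gamma' must be in (0, 1]")
  if (patience < 1L) stop("'patience' must be >= 1")
  structure(list(n = as.integer(n), alpha = alpha, gamma = gamma,
                 patience = as.integer(patience), updateSign = updateSign,
                 maxCycles = as.integer(maxCycles), sdFloor = sdFloor,
                 weightCap = weightCap),
            class = "trainingConfig")
}

#' Normalize a weight vector to unit sum
#'
#' `w / sum(w)`; raw inverse-SD weights can be arbitrarily large or tiny,
#' normalization brings each into `(0, 1]` with total 1.
#'
#' @param w Numeric vector of positive weights.
#' @return Normalized weights summing to 1.
#' @export
normalizeWeights <- function(w) {
  if (any(w < 0)) stop("weights must be non-negative")
  s <- sum(w)
  if (s == 0) stop("cannot normalize an all-zero weight vector")
  w / s
}

#' Inverse-standard-deviation weights from a retrieved-nodule matrix
#'
#' Projects each attribute column of the `n x a` retrieved-nodule matrix,
#' takes the sample standard deviation of the projection and assigns the
#' attribute the weight `1 / sd`: attributes whose values are homogeneous
#' among the retrieved neighbors (good local indicators) get large
#' weights, widely dispersed attributes get small ones. SDs are floored at
#' `sdFloor` so a constant column yields a large finite weight, and after
#' unit-sum normalization no single weight may exceed `weightCap` (excess
#' is redistributed by renormalization).
#'
#' @param R Numeric matrix of retrieved attribute values (n >= 2 rows).
#' @param sdFloor SD floor for constant columns (default 1e-6).
#' @param weightCap Cap on any single normalized weight (default 0.99).
#' @return Normalized weight vector (`WCurrent`), one entry per attribute.
#' @export
isdWeights <- function(R, sdFloor = 1e-6, weightCap = 0.99) {
  if (nrow(R) < 2L) stop("need >= 2 retrieved nodules to estimate SDs")
  sds <- pmax(apply(R, 2, stats::sd), sdFloor)
  w <- normalizeWeights(1 / sds)
  # cap-and-redistribute: capped entries are pinned at weightCap and the
  # remaining mass is shared proportionally among the others
  if (length(w) > 1L && max(w) > weightCap) {
    capped <- rep(FALSE, length(w))
    repeat {
      capped <- capped | w > weightCap
      rest <- 1 - weightCap * sum(capped)
      if (rest <= 0) { w <- rep(1 / length(w), length(w)); break }
      w[capped] <- weightCap
      w[!capped] <- w[!capped] * rest / sum(w[!capped])
      if (all(w[!capped] <= weightCap)) break
    }
  }
  w
}

#' Update the weight memory from the current iteration's weights
#'
#' Blends the learning memory `W` with the current iteration's
#' inverse-SD weights `WCurrent`. The convergent form
#' `W + alpha * (WCurrent - W)` moves the memory towards what the current
#' neighborhood indicates; the `"printed"` form `W + alpha * (W -
#' WCurrent)` applies the update with the opposite sense. Either result is
#' clipped at 0 (weights must stay non-negative) and renormalized to unit
#' sum.
#'
#' @param W Current memory weights (unit sum).
#' @param WCurrent Current-iteration weights (unit sum).
#' @param alpha Adjust factor in `(0, 1)`.
#' @param updateSign `"convergent"` or `"printed"`.
#' @return Updated, normalized weight vector `W*`.
#' @export
updateWeights <- function(W, WCurrent, alpha,
                          updateSign = c("convergent", "printed")) {
  updateSign <- match.arg(updateSign)
  if (length(W) != length(WCurrent))
    stop("'W' and 'WCurrent' must have equal length")
  delta <- if (updateSign == "convergent") WCurrent - W else W - WCurrent
  normalizeWeights(pmax(W + alpha * delta, 0))
}

#' Evaluation stage: score a weight vector on the evaluation database
#'
#' Iterates over the evaluation database by leave-one-out, retrieves the
#' `n` most similar nodules for each query under the weights `W`, maps
#' their malignancies to relevance rewards and computes the discounted
#' gain; the stage value `v` is the mean gain over queries (comparable
#' across database sizes).
#'
#' @param evalDb Normalized [FeatureTable-class].
#' @param W Non-negative unit-sum weight vector.
#' @param config A [trainingConfig()].
#' @return Single numeric evaluation value `v`.
#' @export
evaluationStage <- function(evalDb, W, config = trainingConfig()) {
  X <- featureMatrix(evalDb)
  mal <- malignancy(evalDb)
  ids <- rownames(X)
  N <- nrow(X)
  if (N < 2L) stop("evaluation database is empty or too small")
  if (config$n > N - 1L)
    stop("'n' exceeds the evaluation database size minus one")
  gains <- vapply(seq_len(N), function(q) {
    cand <- setdiff(seq_len(N), q)
    d <- .wedToAll(X[q, ], X[cand, , drop = FALSE], W)
    ord <- cand[order(d, ids[cand])][seq_len(config$n)]
    discountedGain(rewardValue(mal[q], mal[ord]), config$gamma)
  }, numeric(1))
  mean(gains)
}

#' Training stage: one leave-one-out pass of weight updates
#'
#' For each training nodule in turn, retrieves its `n` nearest neighbors
#' under the running weights, computes the inverse-SD weights of the
#' retrieved matrix and folds them into the running memory with
#' [updateWeights()] (online update after every query). Returns the
#' post-loop weights.
#'
#' @param trainDb Normalized [FeatureTable-class].
#' @param W Initial weights for the pass (unit sum).
#' @param config A [trainingConfig()].
#' @return Updated weight vector.
#' @export
trainingStage <- function(trainDb, W, config = trainingConfig()) {
  X <- featureMatrix(trainDb)
  ids <- rownames(X)
  N <- nrow(X)
  if (N < config$n + 1L)
    stop("training database must hold more than 'n' nodules")
  for (q in seq_len(N)) {
    cand <- setdiff(seq_len(N), q)
    d <- .wedToAll(X[q, ], X[cand, , drop = FALSE], W)
    ord <- cand[order(d, ids[cand])][seq_len(config$n)]
    WCurrent <- isdWeights(X[ord, , drop = FALSE], config$sdFloor,
                           config$weightCap)
    W <- updateWeights(W, WCurrent, config$alpha, config$updateSign)
  }
  W
}

#' Run the cyclic evaluation / training weight-learning process
#'
#' Starting from uniform weights `1/a`, alternates an evaluation stage
#' (scoring the current weights on the evaluation database) and a training
#' stage (one leave-one-out pass of inverse-SD updates on the training
#' database). The best-scoring weights seen so far are tracked; the
#' process stops once `patience` consecutive cycles pass without the best
#' evaluation value improving (or at `maxCycles`).
#'
#' @param trainDb,evalDb Normalized, disjoint [FeatureTable-class] objects.
#' @param config A [trainingConfig()].
#' @param verbose Print per-cycle progress.
#' @return List with `WBest` (best weights), `vBest` (their evaluation
#'   value), `history` (`data.frame` of `cycle`, `v`, `vBest`) and
#'   `weights` (matrix of per-cycle weight vectors).
#' @export
runCycle <- function(trainDb, evalDb, config = trainingConfig(),
                     verbose = FALSE) {
  a <- ncol(featureMatrix(trainDb))
  stopifnot(a == ncol(featureMatrix(evalDb)))
  W <- rep(1 / a, a)
  vBest <- -Inf
  WBest <- W
  sinceImprovement <- 0L
  hist <- list()
  wlog <- list()
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    v <- evaluationStage(evalDb, W, config)
    if (v > vBest) {
      vBest <- v
      WBest <- W
      sinceImprovement <- 0L
    } else {
      sinceImprovement <- sinceImprovement + 1L
    }
    hist[[cycle]] <- data.frame(cycle = cycle, v = v, vBest = vBest)
    wlog[[cycle]] <- W
    if (verbose)
      message(sprintf("cycle %d: v = %.6f (best %.6f)", cycle, v, vBest))
    if (sinceImprovement >= config$patience || cycle >= config$maxCycles)
      break
    W <- trainingStage(trainDb, W, config)
  }
  weights <- do.call(rbind, wlog)
  colnames(weights) <- colnames(featureMatrix(trainDb))
  list(WBest = WBest, vBest = vBest, history = do.call(rbind, hist),
       weights = weights)
}

#' Write a learning-run history as JSON and weights as CSV
#'
#' The JSON file records the configuration, the per-cycle evaluation
#' values and weight vectors, and the best weights; the CSV holds
#' `attribute,weight` rows for `WBest`.
#'
#' @param run Result of [runCycle()].
#' @param config The [trainingConfig()] used.
#' @param jsonPath,csvPath Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
writeRunArtifacts <- function(run, config, jsonPath = NULL, csvPath = NULL) {
  if (!is.null(jsonPath)) {
    cycles <- lapply(seq_len(nrow(run$history)), function(i)
      list(index = run$history$cycle[i], v = run$history$v[i],
           W = as.numeric(run$weights[i, ])))
    jsonlite::write_json(list(config = unclass(config), cycles = cycles,
                              W_best = as.numeric(run$WBest),
                              v_best = run$vBest),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csvPath)) {
    utils::write.csv(data.frame(attribute = names(run$WBest) %||%
                                  colnames(run$weights),
                                weight = as.numeric(run$WBest)),
                     csvPath, row.names = FALSE, quote = FALSE)
  }
  invisible(c(jsonPath, csvPath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
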