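test_that("the reward policy follows the malignancy relevance ladder", {
  # malignant-side queries
  expect_equal(rewardValue(5L, 5L), 4)
  expect_equal(rewardValue(5L, 4L), 2)
  expect_equal(rewardValue(4L, 5L), 4)
  expect_equal(rewardValue(4L, 4L), 2)
  expect_equal(rewardValue(4L, c(2L, 1L)), c(0, 0))
  # benign-side queries
  expect_equal(rewardValue(1L, 1L), 4)
  expect_equal(rewardValue(1L, 2L), 2)
  expect_equal(rewardValue(2L, 1L), 4)
  expect_equal(rewardValue(2L, c(2L, 4L, 5L)), c(2, 0, 0))
  expect_error(rewardValue(3L, 5L), "\\{1, 2, 4, 5\\}")
  expect_error(rewardValue(5L, 3L), "\\{1, 2, 4, 5\\}")
})

test_that("discounted gain weights early ranks more heavily", {
  expect_equal(discountedGain(c(4, 4, 4), 1), 12)
  expect_equal(discountedGain(c(4, 2, 0), 0.8), 4.48)
  expect_equal(discountedGain(rep(0, 7), 0.5), 0)
  expect_error(discountedGain(c(4), 0), "gamma")
  expect_error(discountedGain(c(4), 1.2), "gamma")

  # moving a positive reward one rank earlier strictly increases the gain
  set.seed(13)
  for (rep in 1:50) {
    s <- sample(c(0, 2, 4), 8, replace = TRUE)
    pos <- which(s > 0 & c(0, s[-8]) < s)  # a strictly better swap exists
    if (!length(pos) || pos[1] == 1) next
    i <- pos[1]
    s2 <- s; s2[c(i - 1, i)] <- s[c(i, i - 1)]
    expect_gt(discountedGain(s2, 0.8), discountedGain(s, 0.8))
  }
})

test_that("weight normalization returns unit-sum proportions", {
  expect_equal(normalizeWeights(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(normalizeWeights(7), 1)
  set.seed(14)
  for (rep in 1:20)
    expect_lt(abs(sum(normalizeWeights(runif(sample(1:30, 1)))) - 1), 1e-12)
  expect_error(normalizeWeights(c(0, 0)), "all-zero")
  expect_error(normalizeWeights(c(1, -1)), "non-negative")
})

test_that("inverse-SD weights favor low-dispersion attributes", {
  # columns with sample SDs exactly 1 and 3: raw weights (1, 1/3)
  R <- cbind(a = c(0, 1, 2), b = c(0, 3, 6))
  expect_equal(isdWeights(R), c(a = 0.75, b = 0.25))

  # equal dispersion in every column: uniform weights
  Re <- cbind(a = c(0, 1), b = c(5, 6), c = c(-3, -2))
  expect_equal(unname(isdWeights(Re)), rep(1 / 3, 3))

  # a constant column dominates but is capped
  Rc <- cbind(a = c(5, 5, 5), b = c(0, 3, 6))
  wc <- isdWeights(Rc)
  expect_gt(wc[["a"]], wc[["b"]])
  expect_lte(max(wc), 0.99 + 1e-9)
  expect_equal(sum(wc), 1)

  expect_error(isdWeights(Rc[1, , drop = FALSE]), ">= 2")
})

test_that("weight updates blend memory and current weights", {
  W <- c(0.5, 0.5); WC <- c(0.8, 0.2)
  expect_equal(updateWeights(W, WC, 0.3, "convergent"), c(0.59, 0.41))
  expect_equal(updateWeights(W, WC, 0.3, "printed"), c(0.41, 0.59))
  # fixed point for either sign
  expect_equal(updateWeights(WC, WC, 0.3, "convergent"), WC)
  expect_equal(updateWeights(WC, WC, 0.3, "printed"), WC)
  # negative components are clipped before renormalization
  wNeg <- updateWeights(c(0.9, 0.1), c(0.1, 0.9), 0.9, "printed")
  expect_true(all(wNeg >= 0))
  expect_equal(sum(wNeg), 1)
  expect_error(updateWeights(c(1), c(0.5, 0.5), 0.3), "equal length")
})

test_that("training configuration validates its parameters", {
  cfg <- trainingConfig()
  expect_identical(cfg$n, 15L)
  expect_equal(cfg$alpha, 0.3)
  expect_equal(cfg$gamma, 0.8)
  expect_identical(cfg$patience, 100L)
  expect_identical(cfg$updateSign, "convergent")
  expect_error(trainingConfig(alpha = 1.5), "alpha")
  expect_error(trainingConfig(alpha = 0), "alpha")
  expect_error(trainingConfig(gamma = 0), "gamma")
  expect_error(trainingConfig(n = 0), "n")
  expect_error(trainingConfig(patience = 0), "patience")
})

test_that("the evaluation stage matches closed-form gains on separable data", {
  mkdb <- function(centers, mal, perClass = 6, sdv = 1e-3, seed = 15) {
    set.seed(seed)
    X <- do.call(rbind, lapply(centers, function(cc)
      matrix(rnorm(perClass, cc, sdv), perClass, 1)))
    colnames(X) <- "f"
    rownames(X) <- sprintf("n%03d", seq_len(nrow(X)))
    FeatureTable(X, rep(mal, each = perClass))
  }
  cfg <- trainingConfig(n = 3, gamma = 0.8, patience = 5)
  g <- sum(0.8^(1:3))

  # single-class database, rating 5: every retrieved nodule rewards 4
  db5 <- mkdb(0, 5L)
  expect_equal(evaluationStage(db5, 1, cfg), 4 * g, tolerance = 1e-12)

  # four well-separated clusters: neighbors share the query's class, and
  # the same-class reward is 4 for ratings 1 and 5 but 2 for 2 and 4
  db4 <- mkdb(c(0, 100, 200, 300), c(1L, 2L, 4L, 5L))
  expect_equal(evaluationStage(db4, 1, cfg), mean(c(4, 2, 2, 4)) * g,
               tolerance = 1e-10)

  expect_error(evaluationStage(db5, 1, trainingConfig(n = 10)), "exceeds")
})

test_that("training pulls weight onto the informative attribute", {
  set.seed(16)
  # attribute 1 tight within class, attribute 2 pure noise
  gen <- generateFeatureTable(perClass = 20, nAttr = 2, nInformative = 1,
                              seed = 16)
  db <- gen$table
  cfg <- trainingConfig(n = 10, patience = 5)
  W0 <- c(0.5, 0.5)
  W1 <- trainingStage(db, W0, cfg)
  expect_gt(W1[[1]], W0[[1]])
  expect_equal(sum(W1), 1)
  # deterministic: no randomness inside the stage
  expect_identical(W1, trainingStage(db, W0, cfg))
  # a vanishing adjust factor leaves the weights essentially unchanged
  Wfreeze <- trainingStage(db, W0, trainingConfig(n = 10, alpha = 1e-9))
  expect_equal(unname(Wfreeze), W0, tolerance = 1e-6)
  expect_error(trainingStage(db[1:5], W0, trainingConfig(n = 10)),
               "more than")
})

test_that("the learning cycle stops on patience and tracks the best weights", {
  # one attribute: weights are pinned at 1, v is constant, patience 1
  # expires after the second cycle
  set.seed(17)
  X <- matrix(rnorm(12), 12, 1, dimnames = list(sprintf("n%02d", 1:12), "f"))
  db <- FeatureTable(X, rep(c(1L, 2L, 4L, 5L), 3))
  run <- runCycle(db, db, trainingConfig(n = 3, patience = 1))
  expect_identical(nrow(run$history), 2L)

  bm <- generateBenchmark(seed = 18)
  cfg <- trainingConfig(n = 15, patience = 10)
  run <- runCycle(trainTable(bm$split), evalTable(bm$split), cfg)
  expect_false(is.unsorted(run$history$vBest))
  expect_lte(nrow(run$history), cfg$maxCycles)
  # the stored best weights reproduce the best evaluation value
  expect_equal(evaluationStage(evalTable(bm$split), run$WBest, cfg),
               run$vBest)
  # the final best beats or matches the uniform-weight start
  expect_gte(run$vBest, run$history$v[1])
  # every logged weight vector is non-negative with unit sum
  expect_true(all(run$weights >= 0))
  expect_equal(unname(rowSums(run$weights)), rep(1, nrow(run$weights)))
})

test_that("run artifacts are written as JSON history and CSV weights", {
  bm <- generateBenchmark(seed = 19)
  cfg <- trainingConfig(n = 15, patience = 3)
  run <- runCycle(trainTable(bm$split), evalTable(bm$split), cfg)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  writeRunArtifacts(run, cfg, jp, cp)
  hist <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(hist$v_best, run$vBest)
  expect_length(hist$cycles$v, nrow(run$history))
  wcsv <- read.csv(cp)
  expect_equal(wcsv$weight, unname(run$WBest))
})
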