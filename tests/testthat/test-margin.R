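# Parametric circle contour, rasterized, for control-point and normal tests.
circleContour <- function(r = 12, c0 = c(20, 20), nAng = 120) {
  th <- seq(0, 2 * pi, length.out = nAng + 1)[-(nAng + 1)]
  pts <- cbind(round(c0[1] + r * sin(th)), round(c0[2] + r * cos(th)))
  pts <- pts[c(TRUE, rowSums(abs(diff(pts))) > 0), ]
  storage.mode(pts) <- "integer"
  pts
}

test_that("control points are spaced p/k pixels apart from the first mark", {
  pts <- matrix(seq_len(200), 100, 2)  # 100-pixel stand-in contour
  idx <- selectControlPoints(pts, 20)
  expect_identical(idx, 1L + 5L * (0:19))

  expect_identical(selectControlPoints(pts[1:20, ], 20), 1:20)
  expect_warning(out <- selectControlPoints(pts[1:15, ], 20), "15")
  expect_identical(out, 1:15)
})

test_that("normal lines are perpendicular to the boundary and inward-ordered", {
  # axis-aligned square: a point mid-way along the top edge gets a vertical
  # normal
  sq <- rbind(cbind(5L, 5:15), cbind(5:15, 15L), cbind(15L, 15:5),
              cbind(15:5, 5L))
  sq <- sq[!duplicated(sq), ]
  topMid <- which(sq[, 1] == 5L & sq[, 2] == 10L)
  seg <- drawNormalLine(sq, topMid, halfLength = 3)
  expect_true(all(seg$pixels[, 2] == 10L))
  # ordered outer (above the edge) to inner (below)
  expect_lt(seg$pixels[1, 1], seg$pixels[nrow(seg$pixels), 1])

  # circle: normals align with the radius within rasterization tolerance
  circ <- circleContour()
  for (i in selectControlPoints(circ, 10)) {
    seg <- drawNormalLine(circ, i, halfLength = 5)
    expect_lte(nrow(seg$pixels), 11)
    radial <- circ[i, ] - c(20, 20)
    radial <- radial / sqrt(sum(radial^2))
    dirs <- sweep(seg$pixels, 2, circ[i, ])
    offAxis <- abs(dirs[, 1] * radial[2] - dirs[, 2] * radial[1])
    expect_lte(max(offAxis), 1.6)  # <= ~1 pixel off the analytic radius
  }

  # coincident tangent neighbors: point skipped with a message
  degen <- matrix(5L, 7, 2)
  expect_message(out <- drawNormalLine(degen, 1, 3), "degenerate")
  expect_null(out)
})

test_that("lung masks keep the dark field plus a dilation rim", {
  img <- matrix(50, 30, 30)
  img[, 21:30] <- 220  # bright chest wall
  m <- buildLungMask(img, dilationRadius = 2)
  expect_true(all(m[, 1:20]))      # lung field kept
  expect_true(all(m[, 21:22]))     # dilation rim
  expect_false(any(m[, 25:30]))    # wall interior excluded

  expect_false(any(buildLungMask(matrix(220, 10, 10))))  # all bright

  m0 <- buildLungMask(img, dilationRadius = 0)
  expect_true(all(m0[, 1:20]) && !any(m0[, 21:30]))  # pure threshold mask

  # a bright nodule enclosed by lung is a filled hole, so it stays inside
  img[14:17, 8:11] <- 220
  expect_true(all(buildLungMask(img, dilationRadius = 0)[14:17, 8:11]))
})

test_that("clipping removes out-of-mask pixels and drops short segments", {
  mask <- matrix(TRUE, 20, 20); mask[, 15:20] <- FALSE
  inside <- list(pixels = cbind(5:9, 5L), point = c(5L, 5L), clipped = FALSE)
  crossing <- list(pixels = cbind(10L, 12:18), point = c(10L, 14L),
                   clipped = FALSE)
  out <- clipSegmentsToLung(list(inside, crossing), mask)
  expect_identical(out[[1]]$pixels, inside$pixels)
  expect_false(out[[1]]$clipped)
  expect_identical(out[[2]]$pixels, cbind(10L, 12:14))
  expect_true(out[[2]]$clipped)

  gone <- list(pixels = cbind(1L, 15:19), point = c(1L, 17L), clipped = FALSE)
  expect_error(clipSegmentsToLung(list(gone), mask), "no usable margin")
})

test_that("intensities pool into one ascending array", {
  img <- matrix(0, 4, 4)
  img[1, 1] <- 5; img[1, 2] <- 1; img[2, 1] <- 3
  segs <- list(list(list(pixels = rbind(c(1L, 1L), c(1L, 2L))),
                    list(pixels = rbind(c(2L, 1L)))))
  expect_identical(collectSortedIntensities(segs, list(img)), c(1, 3, 5))
})

test_that("margin statistics reproduce hand arithmetic", {
  s <- marginStats(c(1, 2, 3, 4))
  expect_equal(unname(s["diffEnds"]), 3)
  expect_equal(unname(s["sumValues"]), 10)
  expect_equal(unname(s["sumSquares"]), 30)
  expect_equal(unname(s["sumLogs"]), log(24))
  expect_equal(unname(s["mean"]), 2.5)
  expect_equal(unname(s["geometricMean"]), 24^(1 / 4))
  expect_equal(unname(s["populationVariance"]), 1.25)
  expect_equal(unname(s["sampleVariance"]), 5 / 3)
  expect_equal(unname(s["standardDeviation"]), sqrt(5 / 3))
  expect_equal(unname(s["secondCentralMoment"]), 3 / 4)
  expect_length(s, 12)

  # zero dispersion: variance 0 and shape statistics 0 by convention
  s0 <- marginStats(c(7, 7, 7, 7))
  expect_equal(unname(s0[c("populationVariance", "sampleVariance",
                           "standardDeviation", "kurtosis", "skewness",
                           "secondCentralMoment")]), rep(0, 6))

  # second central moment over the squared sample SD is (n-1)/n
  set.seed(1)
  for (n in c(2, 5, 9)) {
    a <- sort(runif(n, 10, 50))
    expect_equal(unname(marginStats(a)["secondCentralMoment"]), (n - 1) / n)
  }

  # non-positive values get a +1 offset for the log statistics only
  expect_message(sOff <- marginStats(c(0, 1, 3)), "offset")
  expect_equal(unname(sOff["sumLogs"]), log(1) + log(2) + log(4))
  expect_equal(unname(sOff["geometricMean"]), 8^(1 / 3))
  expect_equal(unname(sOff["sumValues"]), 4)  # untouched

  expect_error(marginStats(c(3, 1)), "sorted")
  expect_error(marginStats(7), "n >= 2")
})

test_that("standard deviation is exactly the square root of sample variance", {
  set.seed(2)
  for (rep in 1:20) {
    a <- sort(rnorm(sample(2:40, 1), 100, 20))
    s <- marginStats(a)
    expect_identical(s[["standardDeviation"]], sqrt(s[["sampleVariance"]]))
  }
})

test_that("margin vectors are deterministic and length 12", {
  ph <- generatePhantom(seed = 21)
  mv1 <- suppressMessages(marginVector(ph$volume, ph$contours))
  mv2 <- suppressMessages(marginVector(ph$volume, ph$contours))
  expect_length(mv1, 12)
  expect_identical(mv1, mv2)
  # positive-contrast nodule: inside end brighter than outside end
  expect_gt(mv1[["diffEnds"]], 0)
})

test_that("sharper margins give higher pooled variance at equal contrast", {
  sharp <- generatePhantom(edgeWidth = 0.5, noiseSd = 2, seed = 31)
  blurred <- generatePhantom(edgeWidth = 4.0, noiseSd = 2, seed = 31)
  mvS <- suppressMessages(marginVector(sharp$volume, sharp$contours))
  mvB <- suppressMessages(marginVector(blurred$volume, blurred$contours))
  expect_gt(mvS[["sampleVariance"]], mvB[["sampleVariance"]])
})

test_that("juxtapleural walls clip normal-line segments", {
  ph <- generatePhantom(wall = TRUE, seed = 41)
  # largest cross-section: the contour there reaches the wall
  big <- which.max(vapply(ph$contours$slices,
                          function(s) nrow(s$points), integer(1)))
  z <- ph$contours$slices[[big]]$sliceIndex
  pts <- ph$contours$slices[[big]]$points
  segs <- lapply(selectControlPoints(pts, 20),
                 function(i) drawNormalLine(pts, i, 6))
  segs <- segs[!vapply(segs, is.null, logical(1))]
  mask <- buildLungMask(ph$volume[, , z])
  kept <- clipSegmentsToLung(segs, mask)
  nShortened <- sum(vapply(kept, function(s) s$clipped, logical(1)))
  nDropped <- length(segs) - length(kept)
  expect_gt(nShortened + nDropped, 0)  # wall-side normals lose pixels
  pixTotal <- function(ss) sum(vapply(ss, function(s) nrow(s$pixels),
                                      integer(1)))
  expect_lt(pixTotal(kept), pixTotal(segs))
  # the margin vector still computes from the surviving segments
  mv <- suppressMessages(marginVector(ph$volume, ph$contours))
  expect_length(mv, 12)
})
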