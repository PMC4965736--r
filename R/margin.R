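#' Select evenly spaced control points along a closed boundary contour
#'
#' Starting at the first marked point, selects `k` points spaced
#' `floor(p / k)` boundary pixels apart along the traversal order of a
#' closed contour of `p` pixels. Contours with fewer than `k` pixels
#' contribute every boundary pixel once, with a warning.
#'
#' @param points `p x 2` matrix of boundary pixel coordinates (row, col) in
#'   traversal order; the first row is the first marked point.
#' @param k Number of control points (default 20).
#' @return Integer indices into `points` of the selected control points.
#' @export
selectControlPoints <- function(points, k = 20L) {
  k <- as.integer(k)
  p <- nrow(points)
  if (p < 1L) stop("empty contour")
  if (p < k) {
    warning(sprintf("contour has %d < %d pixels; using every boundary pixel",
                    p, k))
    return(seq_len(p))
  }
  step <- p %/% k
  1L + step * (seq_len(k) - 1L)
}

#' Draw a digital line normal to the boundary at a control point
#'
#' Estimates the local boundary tangent by central difference over contour
#' neighbors at `+/- tangentOffset`, takes the perpendicular direction
#' oriented towards the contour centroid (inward), and rasterizes a segment
#' extending `halfLength` pixels outward and `halfLength` pixels inward
#' through the control point. Pixels are ordered outer to inner.
#'
#' @param points Closed contour as in [selectControlPoints()].
#' @param index Row index of the control point.
#' @param halfLength Half the segment length in pixels (default 6).
#' @param tangentOffset Contour-neighbor offset for the tangent estimate.
#' @return List with `pixels` (m x 2 integer matrix, outer to inner),
#'   `point`, `clipped = FALSE`; or `NULL` when the tangent is degenerate
#'   (coincident neighbors), with a message.
#' @export
drawNormalLine <- function(points, index, halfLength = 6L,
                           tangentOffset = 2L) {
  p <- nrow(points)
  i0 <- index - 1L  # 0-based for modular arithmetic
  fwd <- points[(i0 + tangentOffset) %% p + 1L, ]
  bwd <- points[(i0 - tangentOffset) %% p + 1L, ]
  tg <- fwd - bwd
  if (all(tg == 0)) {
    message("degenerate tangent at contour index ", index, "; point skipped")
    return(NULL)
  }
  nv <- c(-tg[2], tg[1])
  nv <- nv / sqrt(sum(nv^2))
  ctr <- colMeans(points)
  pt <- as.numeric(points[index, ])
  if (sum((ctr - pt) * nv) < 0) nv <- -nv  # orient inward
  u <- seq.int(-halfLength, halfLength)    # outer -> inner
  pix <- round(cbind(pt[1] + u * nv[1], pt[2] + u * nv[2]))
  keep <- c(TRUE, rowSums(abs(diff(pix))) > 0)
  pix <- pix[keep, , drop = FALSE]
  storage.mode(pix) <- "integer"
  list(pixels = pix, point = points[index, ], clipped = FALSE)
}

#' Build a lung mask for one CT slice
#'
#' Thresholds the slice (lung parenchyma is darker than chest wall),
#' fills enclosed holes so the nodule itself — which appears as a bright
#' hole in the dark lung field — remains inside the mask, and dilates by a
#' disk. Normal-line pixels outside this mask (chest wall, mediastinum) are
#' discarded by [clipSegmentsToLung()].
#'
#' @param sliceImage Numeric matrix of raw stored gray values.
#' @param threshold Absolute intensity threshold; pixels strictly below it
#'   form the lung field. `NULL` (default) picks the threshold
#'   automatically by Otsu's method, which splits the two dominant
#'   histogram modes.
#' @param dilationRadius Disk radius for morphological dilation (default 2);
#'   0 skips dilation.
#' @param fillHoles Fill enclosed holes before dilating (default `TRUE`).
#' @return Logical matrix, `TRUE` where pixels may be kept.
#' @export
buildLungMask <- function(sliceImage, threshold = NULL, dilationRadius = 2L,
                          fillHoles = TRUE) {
  if (is.null(threshold)) {
    lo <- min(sliceImage); hi <- max(sliceImage)
    if (hi == lo) {
      threshold <- lo  # flat image: nothing strictly below
    } else {
      t01 <- EBImage::otsu(EBImage::Image((sliceImage - lo) / (hi - lo)),
                           range = c(0, 1), levels = 256L)
      threshold <- lo + t01 * (hi - lo)
    }
  }
  m <- (sliceImage < threshold) * 1
  if (fillHoles && any(m > 0)) m <- EBImage::fillHull(m)
  if (dilationRadius > 0 && any(m > 0))
    m <- EBImage::dilate(m, EBImage::makeBrush(2L * dilationRadius + 1L,
                                               shape = "disc"))
  matrix(as.logical(m > 0.5), nrow(sliceImage), ncol(sliceImage))
}

#' Clip normal-line segments to the lung mask
#'
#' Removes from each segment the pixels falling outside the lung mask
#' (keeping pixel order), flags segments that lost pixels, and drops
#' segments left with fewer than 2 pixels.
#'
#' @param segments List of segments as returned by [drawNormalLine()].
#' @param mask Logical matrix from [buildLungMask()], aligned with the
#'   segment coordinates (1-based row, col).
#' @return List of surviving segments.
#' @export
clipSegmentsToLung <- function(segments, mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- list()
  for (seg in segments) {
    if (is.null(seg)) next
    px <- seg$pixels
    inb <- px[, 1] >= 1L & px[, 1] <= nr & px[, 2] >= 1L & px[, 2] <= nc
    keep <- inb
    keep[inb] <- mask[cbind(px[inb, 1], px[inb, 2])]
    if (sum(keep) < 2L) next
    seg$clipped <- any(!keep)
    seg$pixels <- px[keep, , drop = FALSE]
    out[[length(out) + 1L]] <- seg
  }
  if (!length(out))
    stop("all normal-line segments were clipped away: no usable margin samples")
  out
}

#' Pool segment pixel intensities into one sorted array
#'
#' Collects the gray values under every surviving normal-line segment, over
#' all slices, into a single array sorted in ascending order. For a bright
#' nodule in a dark lung field the first element is then an outside-nodule
#' intensity and the last an inside-nodule intensity.
#'
#' @param segmentsBySlice Named list: one entry per slice, each a list of
#'   clipped segments.
#' @param sliceImages List of intensity matrices, parallel to
#'   `segmentsBySlice`.
#' @return Sorted numeric vector of pooled intensities.
#' @export
collectSortedIntensities <- function(segmentsBySlice, sliceImages) {
  vals <- unlist(lapply(seq_along(segmentsBySlice), function(s) {
    img <- sliceImages[[s]]
    unlist(lapply(segmentsBySlice[[s]], function(seg)
      img[cbind(seg$pixels[, 1], seg$pixels[, 2])]))
  }))
  if (!length(vals)) stop("no margin intensities collected")
  sort(vals)
}

#' Rasterize contour annotations into a nodule voxel mask
#'
#' Fills each slice's closed boundary contour (hole filling of the contour
#' raster) to produce the segmentation mask used by the texture extractor.
#' The boundary pixels themselves are included; since the annotation
#' convention draws the outline just outside the nodule, the mask is a
#' one-pixel-generous cover of the lesion.
#'
#' @param contours Contour set as used by [marginVector()].
#' @param dims Volume dimensions `c(rows, cols, slices)`.
#' @return Logical 3D array.
#' @export
contoursToMask <- function(contours, dims) {
  mask <- array(FALSE, dims)
  for (sl in contours$slices) {
    m <- matrix(0, dims[1], dims[2])
    m[sl$points] <- 1
    m <- EBImage::fillHull(m)
    mask[, , sl$sliceIndex] <- mask[, , sl$sliceIndex] | (m > 0)
  }
  mask
}

.marginNames <- c("diffEnds", "sumValues", "sumSquares", "sumLogs", "mean",
                  "geometricMean", "populationVariance", "sampleVariance",
                  "standardDeviation", "kurtosis", "skewness",
                  "secondCentralMoment")

#' Twelve margin-sharpness statistics of a sorted intensity array
#'
#' Computes, in fixed order: difference of the two ends `a[n] - a[1]`, sum
#' of values, sum of squares, sum of logs, arithmetic mean, geometric mean,
#' population variance, sample variance `v`, standard deviation
#' `s = sqrt(v)`, kurtosis `m4 / s^4`, skewness `m3 / s^3` and second
#' central moment `m2 / s^2` (central moments `mk` use the `1/n`
#' normalization, `s` the sample SD, so the last equals `(n - 1) / n`).
#'
#' Logs and the geometric mean are taken on raw stored (unsigned) gray
#' values; if any value is non-positive a `+1` offset is applied to the
#' whole array for those two statistics only, with a message. Zero-dispersion
#' arrays get skewness, kurtosis and second central moment 0 by convention.
#'
#' @param a Numeric vector of pooled intensities, sorted ascending, n >= 2.
#' @return Named numeric vector of length 12.
#' @examples
#' marginStats(c(1, 2, 3, 4))
#' @export
marginStats <- function(a) {
  n <- length(a)
  if (n < 2L) stop("intensity array must have n >= 2")
  if (is.unsorted(a)) stop("'a' must be sorted ascending")
  aLog <- a
  if (any(a <= 0)) {
    message("non-positive intensities: +1 offset applied for log statistics")
    aLog <- a + 1
  }
  mu <- mean(a)
  cen <- a - mu
  popVar <- sum(cen^2) / n
  v <- sum(cen^2) / (n - 1)
  s <- sqrt(v)
  if (s == 0) {
    kurt <- skew <- m2n <- 0
  } else {
    kurt <- (sum(cen^4) / n) / s^4
    skew <- (sum(cen^3) / n) / s^3
    m2n <- (sum(cen^2) / n) / s^2
  }
  out <- c(a[n] - a[1], sum(a), sum(a^2), sum(log(aLog)), mu,
           exp(mean(log(aLog))), popVar, v, s, kurt, skew, m2n)
  names(out) <- .marginNames
  out
}

#' 12-attribute margin-sharpness vector of a nodule
#'
#' Full margin-sharpness analysis over all annotated slices: control points
#' on each slice contour, boundary-normal line segments, lung-mask
#' clipping, pooling of the surviving segment intensities into one sorted
#' array, and the twelve statistics of [marginStats()].
#'
#' @param rawVolume 3D numeric array of raw slice images (third axis =
#'   slices).
#' @param contours A contour set as returned by [readContours()] or
#'   [generatePhantom()]: list with `slices`, each holding `sliceIndex`
#'   (1-based) and `points` (p x 2 matrix, 1-based row/col, traversal
#'   order, first row = first marked point).
#' @param k Control points per slice (default 20).
#' @param halfLength Normal-line half length in pixels (default 6).
#' @param tangentOffset Neighbor offset for the tangent estimate (default 2).
#' @param threshold,dilationRadius,fillHoles Passed to [buildLungMask()].
#' @return Named numeric vector of length 12.
#' @export
marginVector <- function(rawVolume, contours, k = 20L, halfLength = 6L,
                         tangentOffset = 2L, threshold = NULL,
                         dilationRadius = 2L, fillHoles = TRUE) {
  segsBySlice <- list()
  imgs <- list()
  for (sl in contours$slices) {
    pts <- sl$points
    img <- rawVolume[, , sl$sliceIndex]
    cps <- selectControlPoints(pts, k)
    segs <- lapply(cps, function(i)
      drawNormalLine(pts, i, halfLength, tangentOffset))
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (!length(segs)) next
    mask <- buildLungMask(img, threshold, dilationRadius, fillHoles)
    segs <- tryCatch(clipSegmentsToLung(segs, mask),
                     error = function(e) list())
    if (!length(segs)) next
    imgs[[length(imgs) + 1L]] <- img
    segsBySlice[[length(segsBySlice) + 1L]] <- segs
  }
  if (!length(segsBySlice))
    stop("no usable margin samples on any slice")
  marginStats(collectSortedIntensities(segsBySlice, imgs))
}
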