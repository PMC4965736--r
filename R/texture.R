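#' Quantize a raw intensity volume into gray-level bins
#'
#' Linearly bins the intensity range of the masked voxels into `levels`
#' equal-width bins. The bin boundaries are half-open on the left, so the
#' range midpoint of a two-bin quantization falls in the lower bin, and a
#' quantization with as many levels as distinct consecutive input values is
#' the identity. Constant volumes map entirely to bin 0. Values of unmasked
#' voxels are binned with the same rule but never enter any co-occurrence
#' count.
#'
#' @param rawVolume 3D numeric array of stored gray values (e.g. CT).
#' @param mask Logical array of the same shape marking nodule voxels;
#'   defaults to all `TRUE`.
#' @param levels Number of gray-level bins `L` (>= 2). 64 levels keep the
#'   co-occurrence matrices of small nodules reasonably dense.
#' @return A [GrayVolume-class] with values in `[0, levels - 1]`.
#' @examples
#' v <- array(c(0, 100, 200, 200), c(2, 2, 1))
#' voxelData(quantizeVolume(v, levels = 2))[, , 1]
#' @export
quantizeVolume <- function(rawVolume, mask = NULL, levels = 64L) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("'levels' must be >= 2")
  if (is.null(mask)) mask <- array(TRUE, dim(rawVolume))
  if (!any(mask)) stop("mask contains no segmented voxels")
  lo <- min(rawVolume[mask])
  hi <- max(rawVolume[mask])
  if (hi == lo) {
    q <- array(0L, dim(rawVolume))
  } else {
    q <- ceiling((rawVolume - lo) / (hi - lo) * levels) - 1L
    q <- pmin(pmax(q, 0L), levels - 1L)
    q <- array(as.integer(q), dim(rawVolume))
  }
  GrayVolume(q, levels = levels, mask = mask)
}

## In-plane (row, col) offset for each orientation; rows grow downward so a
## 45 degree direction is (-d, +d) in array coordinates.
.inplaneOffset <- function(orientation, distance) {
  d <- as.integer(distance)
  switch(as.character(orientation),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("orientation must be one of 0, 45, 90, 135 degrees"))
}

## Displacement set for one orientation matrix. "full3d" folds the
## between-slice pairs (same in-plane offset one slice up, and the purely
## axial neighbor) into the orientation's matrix so the attribute count
## stays at 9 statistics x 4 orientations.
.offsetSet <- function(orientation, distance, pairMode) {
  ip <- .inplaneOffset(orientation, distance)
  offs <- list(c(ip, 0L))
  if (pairMode == "full3d")
    offs <- c(offs, list(c(ip, 1L)), list(c(0L, 0L, 1L)))
  offs
}

## Count ordered voxel pairs (one direction) at a single 3D displacement,
## restricted to the mask, via aligned sub-array extraction.
.countPairs <- function(vox, mask, off, L) {
  d <- dim(vox)
  r <- seq_len(d[1]); r <- r[r + off[1] >= 1L & r + off[1] <= d[1]]
  c_ <- seq_len(d[2]); c_ <- c_[c_ + off[2] >= 1L & c_ + off[2] <= d[2]]
  s <- seq_len(d[3]); s <- s[s + off[3] >= 1L & s + off[3] <= d[3]]
  if (!length(r) || !length(c_) || !length(s))
    return(matrix(0L, L, L))
  a <- vox[r, c_, s, drop = FALSE]
  b <- vox[r + off[1], c_ + off[2], s + off[3], drop = FALSE]
  keep <- mask[r, c_, s, drop = FALSE] &
    mask[r + off[1], c_ + off[2], s + off[3], drop = FALSE]
  i <- a[keep]; j <- b[keep]
  matrix(tabulate(i * L + j + 1L, nbins = L * L), L, L, byrow = TRUE)
}

#' Build a 3D gray-level co-occurrence matrix
#'
#' Counts every gray-level pair of masked voxels at the in-plane offset of
#' the given orientation and distance, accumulated over all slices. With
#' `pairMode = "full3d"` (the default) the between-slice pairs of the 3D
#' extension are folded into the same matrix: the in-plane offset applied
#' across adjacent slices plus the purely axial neighbor. Pairs are counted
#' symmetrically (both directions) and counts are normalized to
#' probabilities.
#'
#' @param volume A [GrayVolume-class].
#' @param orientation In-plane orientation in degrees: 0, 45, 90 or 135.
#' @param distance Pixel offset `d` (>= 1).
#' @param pairMode `"full3d"` or `"inplane"`.
#' @return A [CooccurrenceMatrix-class].
#' @examples
#' gv <- GrayVolume(array(c(0L, 1L, 0L, 1L), c(1, 4, 1)), levels = 2)
#' comMatrix(buildCOM(gv, 0))
#' @export
buildCOM <- function(volume, orientation, distance = 1L,
                     pairMode = c("full3d", "inplane")) {
  stopifnot(is(volume, "GrayVolume"))
  pairMode <- match.arg(pairMode)
  if (distance < 1L) stop("'distance' must be >= 1")
  L <- volume@levels
  counts <- matrix(0L, L, L)
  for (off in .offsetSet(orientation, distance, pairMode))
    counts <- counts + .countPairs(volume@voxels, volume@mask, off, L)
  counts <- counts + t(counts)  # symmetric counting
  total <- sum(counts)
  if (total == 0L)
    stop("no valid voxel pairs at this offset: insufficient support")
  new("CooccurrenceMatrix", probs = counts / total, counts = counts,
      orientation = as.numeric(orientation), distance = as.integer(distance),
      pairMode = pairMode)
}

#' Marginal statistics of a co-occurrence matrix
#'
#' Row and column marginals `Cx(i)`, `Cy(j)`, their means and dispersions.
#' Note that `sigmaX` and `sigmaY` are marginal variances,
#' `sum((i - muX)^2 * Cx(i))`; the correlation statistic divides by
#' `sqrt(sigmaX * sigmaY)`, i.e. the product of the marginal standard
#' deviations.
#'
#' @param com A [CooccurrenceMatrix-class].
#' @return List with `Cx`, `Cy`, `muX`, `muY`, `sigmaX`, `sigmaY`. Gray
#'   levels are indexed `0 .. L-1`.
#' @export
comMarginals <- function(com) {
  C <- com@probs
  L <- nrow(C)
  idx <- 0:(L - 1)
  Cx <- rowSums(C)
  Cy <- colSums(C)
  muX <- sum(idx * Cx)
  muY <- sum(idx * Cy)
  list(Cx = Cx, Cy = Cy, muX = muX, muY = muY,
       sigmaX = sum((idx - muX)^2 * Cx),
       sigmaY = sum((idx - muY)^2 * Cy))
}

.haralickNames <- c("energy", "entropy", "inverseDifferenceMoment",
                    "inertia", "variance", "shade", "prominence",
                    "correlation", "homogeneity")

#' Nine second-order texture statistics of a co-occurrence matrix
#'
#' Computes energy, entropy (base-2 logarithm, zero cells contribute 0),
#' inverse difference moment, inertia (contrast), variance (about the row
#' marginal mean), cluster shade, cluster prominence, correlation and
#' homogeneity.
#'
#' Two correlation conventions are available. `"printed"` is
#' `-sum((i - muX)(j - muY) C(i,j)) / sqrt(sigmaX * sigmaY)` with a leading
#' minus sign; `"haralick"` is the same expression without it (the standard
#' product-moment form). When `sigmaX * sigmaY = 0` (a single-level matrix)
#' correlation is defined as 0.
#'
#' @param com A [CooccurrenceMatrix-class].
#' @param correlationConvention `"printed"` (default) or `"haralick"`.
#' @return Named numeric vector of the nine statistics, in the order
#'   energy, entropy, inverseDifferenceMoment, inertia, variance, shade,
#'   prominence, correlation, homogeneity.
#' @examples
#' gv <- GrayVolume(array(0L, c(2, 2, 1)), levels = 2)
#' haralickStats(buildCOM(gv, 0))  # one-hot: energy 1, entropy 0
#' @export
haralickStats <- function(com, correlationConvention = c("printed", "haralick")) {
  correlationConvention <- match.arg(correlationConvention)
  C <- com@probs
  L <- nrow(C)
  idx <- 0:(L - 1)
  I <- matrix(idx, L, L)
  J <- matrix(idx, L, L, byrow = TRUE)
  m <- comMarginals(com)
  nz <- C > 0
  entropy <- -sum(C[nz] * log2(C[nz]))
  cp <- I + J - m$muX - m$muY
  den <- sqrt(m$sigmaX * m$sigmaY)
  corrRaw <- if (den == 0) 0 else sum((I - m$muX) * (J - m$muY) * C) / den
  correlation <- if (correlationConvention == "printed") -corrRaw else corrRaw
  out <- c(sum(C^2),
           entropy,
           sum(C / (1 + (I - J)^2)),
           sum((I - J)^2 * C),
           sum((I - m$muX)^2 * C),
           sum(cp^3 * C),
           sum(cp^4 * C),
           correlation,
           sum(C / (1 + abs(I - J))))
  names(out) <- .haralickNames
  out
}

#' 36-attribute volumetric texture vector
#'
#' Builds a co-occurrence matrix per orientation (0, 45, 90, 135 degrees)
#' and concatenates the nine statistics of each, orientation-major, into a
#' 36-dimension texture attribute vector.
#'
#' @param volume A [GrayVolume-class].
#' @param distance Pixel offset `d` passed to [buildCOM()].
#' @param pairMode `"full3d"` or `"inplane"`; see [buildCOM()].
#' @param correlationConvention Passed to [haralickStats()].
#' @return Named numeric vector of length 36 (`theta0_energy`, ...,
#'   `theta135_homogeneity`).
#' @export
textureVector <- function(volume, distance = 1L,
                          pairMode = c("full3d", "inplane"),
                          correlationConvention = c("printed", "haralick")) {
  pairMode <- match.arg(pairMode)
  correlationConvention <- match.arg(correlationConvention)
  out <- unlist(lapply(c(0, 45, 90, 135), function(theta) {
    s <- haralickStats(buildCOM(volume, theta, distance, pairMode),
                       correlationConvention)
    names(s) <- paste0("theta", theta, "_", names(s))
    s
  }))
  stopifnot(length(out) == 36L)
  out
}
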