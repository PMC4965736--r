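#' Generate a class-structured synthetic feature table
#'
#' Emulates the premise of the weight-learning method: nodules of the same
#' malignancy have similar attribute vectors on the informative attributes
#' (low within-class dispersion) while noise attributes are widely
#' dispersed and carry no class signal. Class means on informative
#' attributes are ordered along the malignancy scale 1 < 2 < 4 < 5, so
#' moderately relevant neighbors really are nearer than irrelevant ones.
#'
#' @param classes Malignancy labels (default `c(1, 2, 4, 5)`).
#' @param perClass Nodules per class (default 50).
#' @param nAttr Total attribute count (default 8).
#' @param nInformative Number of informative attributes, placed first
#'   (default 2).
#' @param sdInformative Within-class SD of informative attributes
#'   (default 0.2).
#' @param sdNoise SD of noise attributes (default 2.0).
#' @param classSep Spacing of consecutive class means on informative
#'   attributes (default 2.0); noise attributes have identical means.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return List with `table` (a [FeatureTable-class], kind `"custom"`) and
#'   `informative` (the informative attribute names).
#' @export
generateFeatureTable <- function(classes = c(1L, 2L, 4L, 5L), perClass = 50L,
                                 nAttr = 8L, nInformative = 2L,
                                 sdInformative = 0.2, sdNoise = 2.0,
                                 classSep = 2.0, seed = 1L) {
  stopifnot(nInformative <= nAttr, sdInformative > 0, sdNoise > 0)
  set.seed(as.integer(seed))
  classes <- sort(as.integer(classes))
  nTot <- length(classes) * perClass
  attrNames <- c(sprintf("inf%02d", seq_len(nInformative)),
                 sprintf("noise%02d", seq_len(nAttr - nInformative)))
  X <- matrix(NA_real_, nTot, nAttr, dimnames = list(NULL, attrNames))
  mal <- integer(nTot)
  row <- 0L
  for (ci in seq_along(classes)) {
    idx <- row + seq_len(perClass)
    infMean <- (ci - 1L) * classSep
    for (f in seq_len(nAttr)) {
      X[idx, f] <- if (f <= nInformative)
        stats::rnorm(perClass, infMean, sdInformative)
      else
        stats::rnorm(perClass, 0, sdNoise)
    }
    mal[idx] <- classes[ci]
    row <- row + perClass
  }
  rownames(X) <- sprintf("N%04d", seq_len(nTot))
  list(table = FeatureTable(X, mal, vectorKind = "custom"),
       informative = attrNames[seq_len(nInformative)])
}

## Per-slice elliptical contour just outside the lesion cross-section,
## rasterized from angle 0 (the "first marked point") counter-clockwise.
.ellipseContour <- function(cr, cc, ar, br) {
  nAng <- max(24L, ceiling(2 * pi * max(ar, br)) * 2L)
  th <- seq(0, 2 * pi, length.out = nAng + 1L)[-(nAng + 1L)]
  pts <- cbind(round(cr + ar * sin(th)), round(cc + br * cos(th)))
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > 1L && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  storage.mode(pts) <- "integer"
  pts
}

#' Generate a voxel nodule phantom with controllable margin sharpness
#'
#' An ellipsoidal lesion with a sigmoid radial intensity profile of the
#' stated edge width, additive Gaussian noise, per-slice boundary contours
#' drawn just outside the lesion, and an optional bright wall plane
#' emulating a juxtapleural nodule whose margin normals must be
#' mask-clipped.
#'
#' @param shape Volume dimensions `c(rows, cols, slices)`.
#' @param radii Ellipsoid semi-axes in voxels `c(row, col, slice)`.
#' @param center Lesion center; default volume center.
#' @param edgeWidth Sigmoid transition width in voxels (> 0). Small values
#'   give sharp margins, large values blurred ones.
#' @param insideMean,outsideMean Mean stored intensity inside / outside the
#'   lesion.
#' @param noiseSd SD of additive Gaussian noise (drives texture).
#' @param wall Add a bright wall plane (juxtapleural case)?
#' @param wallStart First column of the wall; default just past the lesion.
#' @param wallIntensity Stored intensity of the wall.
#' @param seed Integer seed.
#' @return List with `volume` (3D array of stored intensities >= 0),
#'   `mask` (logical lesion mask), `contours` (1-based contour set with
#'   `noduleId`, `malignancy = NA`, `slices`), and `spec` (the arguments).
#' @export
generatePhantom <- function(shape = c(40L, 40L, 7L), radii = c(10, 8, 2.4),
                            center = NULL, edgeWidth = 1.5,
                            insideMean = 200, outsideMean = 60, noiseSd = 5,
                            wall = FALSE, wallStart = NULL,
                            wallIntensity = 230, seed = 1L) {
  stopifnot(edgeWidth > 0, all(radii > 0))
  if (is.null(center)) center <- (shape + 1) / 2
  if (any(center + radii > shape + 0.5) || any(center - radii < 0.5))
    stop("ellipsoid radii must fit inside the volume")
  set.seed(as.integer(seed))
  r <- slice.index(array(0, shape), 1)
  cc <- slice.index(array(0, shape), 2)
  s <- slice.index(array(0, shape), 3)
  rho <- sqrt(((r - center[1]) / radii[1])^2 +
              ((cc - center[2]) / radii[2])^2 +
              ((s - center[3]) / radii[3])^2)
  sdist <- (1 - rho) * min(radii)  # approx signed distance to the surface
  vol <- outsideMean + (insideMean - outsideMean) *
    stats::plogis(sdist / edgeWidth)
  mask <- rho <= 1
  if (wall) {
    if (is.null(wallStart))
      wallStart <- min(shape[2], ceiling(center[2] + radii[2]))
    vol[, wallStart:shape[2], ] <- wallIntensity
  }
  vol <- vol + stats::rnorm(length(vol), 0, noiseSd)
  vol <- array(pmax(round(vol), 0), shape)
  slices <- list()
  for (z in seq_len(shape[3])) {
    dz2 <- ((z - center[3]) / radii[3])^2
    if (dz2 >= 1) next
    scl <- sqrt(1 - dz2)
    pts <- .ellipseContour(center[1], center[2],
                           radii[1] * scl + 1, radii[2] * scl + 1)
    if (nrow(pts) < 4L) next
    slices[[length(slices) + 1L]] <- list(sliceIndex = z, points = pts)
  }
  list(volume = vol, mask = mask,
       contours = list(noduleId = "phantom", malignancy = NA_integer_,
                       slices = slices),
       spec = list(shape = shape, radii = radii, center = center,
                   edgeWidth = edgeWidth, insideMean = insideMean,
                   outsideMean = outsideMean, noiseSd = noiseSd,
                   wall = wall, seed = seed))
}

#' Write a phantom as a multi-page TIFF plus contour JSON
#'
#' Slices are written as 16-bit grayscale pages (stored intensities scaled
#' by the volume maximum); contours go to the standard 0-based JSON format
#' of [writeContours()].
#'
#' @param phantom Result of [generatePhantom()].
#' @param tiffPath,jsonPath Output paths.
#' @return Invisibly, the written paths.
#' @export
writePhantom <- function(phantom, tiffPath, jsonPath) {
  hi <- max(phantom$volume, 1)
  pages <- lapply(seq_len(dim(phantom$volume)[3]),
                  function(z) phantom$volume[, , z] / hi)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 16L)
  writeContours(phantom$contours, jsonPath)
  invisible(c(tiffPath, jsonPath))
}

#' Read a multi-page TIFF written by [writePhantom()]
#'
#' @param tiffPath TIFF path.
#' @param scale Factor to restore stored intensities (default 65535,
#'   returning values on the written 16-bit grid).
#' @return 3D numeric array (third axis = slices).
#' @export
readVolumeTIFF <- function(tiffPath, scale = 65535) {
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  array(unlist(pages), c(dim(pages[[1]]), length(pages))) * scale
}

#' Generate the seeded synthetic retrieval benchmark
#'
#' A class-structured feature table (four malignancy classes, informative
#' plus noise attributes) split into training / evaluation / validation
#' databases mirroring the full-scale 65/65/30-per-class protocol at a
#' reduced default of 20/20/10, then z-score normalized with a model fit
#' on the training subset only.
#'
#' @param seed Integer seed driving both generation and the split.
#' @param counts Per-class subset sizes (default
#'   `c(train = 20, eval = 20, valid = 10)`).
#' @param fullScale Use the full-scale counts 65/65/30 instead.
#' @param ... Further arguments passed to [generateFeatureTable()].
#' @return List with `split` (a [DatabaseSplit-class], normalized),
#'   `informative` (informative attribute names), `model` (the
#'   [NormalizationModel-class]) and `seed`.
#' @export
generateBenchmark <- function(seed = 1L,
                              counts = c(train = 20L, eval = 20L,
                                         valid = 10L),
                              fullScale = FALSE, ...) {
  if (fullScale) counts <- c(train = 65L, eval = 65L, valid = 30L)
  gen <- generateFeatureTable(perClass = sum(counts), seed = seed, ...)
  split <- makeSplit(gen$table, counts, seed = seed)
  model <- fitZscore(split@train)
  norm <- new("DatabaseSplit",
              train = applyZscore(model, split@train),
              eval = applyZscore(model, split@eval),
              valid = applyZscore(model, split@valid),
              manifest = split@manifest)
  list(split = norm, informative = gen$informative, model = model,
       seed = as.integer(seed))
}
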