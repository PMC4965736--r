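# Independent oracles: brute-force implementations kept deliberately
# separate from the package code paths they check.

# Exhaustive pair enumeration for the co-occurrence counts: triple loop over
# voxels, both directions of every displacement, mask-restricted.
oracleCOMCounts <- function(vox, mask, orientation, distance = 1L,
                            pairMode = "full3d") {
  L <- max(vox) + 1L
  ip <- switch(as.character(orientation),
               "0" = c(0L, distance), "45" = c(-distance, distance),
               "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  offs <- list(c(ip, 0L))
  if (pairMode == "full3d") offs <- c(offs, list(c(ip, 1L)), list(c(0L, 0L, 1L)))
  d <- dim(vox)
  counts <- matrix(0L, L, L)
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) for (s in seq_len(d[3])) {
    if (!mask[r, cc, s]) next
    for (off in offs) for (sgn in c(1L, -1L)) {
      r2 <- r + sgn * off[1]; c2 <- cc + sgn * off[2]; s2 <- s + sgn * off[3]
      if (r2 < 1L || r2 > d[1] || c2 < 1L || c2 > d[2] ||
          s2 < 1L || s2 > d[3]) next
      if (!mask[r2, c2, s2]) next
      i <- vox[r, cc, s] + 1L; j <- vox[r2, c2, s2] + 1L
      counts[i, j] <- counts[i, j] + 1L
    }
  }
  counts
}

# Literal transcription of the nine texture statistics and their marginals,
# evaluated with explicit scalar loops.
oracleHaralick <- function(C, convention = "printed") {
  L <- nrow(C)
  Cx <- vapply(1:L, function(i) sum(C[i, ]), numeric(1))
  Cy <- vapply(1:L, function(j) sum(C[, j]), numeric(1))
  mux <- sum(vapply(1:L, function(i) (i - 1) * Cx[i], numeric(1)))
  muy <- sum(vapply(1:L, function(j) (j - 1) * Cy[j], numeric(1)))
  sigx <- sum(vapply(1:L, function(i) (i - 1 - mux)^2 * Cx[i], numeric(1)))
  sigy <- sum(vapply(1:L, function(j) (j - 1 - muy)^2 * Cy[j], numeric(1)))
  energy <- entropy <- idm <- inertia <- varc <- shade <- prom <- 0
  corrNum <- homog <- 0
  for (ii in 1:L) for (jj in 1:L) {
    i <- ii - 1; j <- jj - 1; c <- C[ii, jj]
    energy <- energy + c^2
    if (c > 0) entropy <- entropy - c * log2(c)
    idm <- idm + c / (1 + (i - j)^2)
    inertia <- inertia + (i - j)^2 * c
    varc <- varc + (i - mux)^2 * c
    shade <- shade + (i + j - mux - muy)^3 * c
    prom <- prom + (i + j - mux - muy)^4 * c
    corrNum <- corrNum + (i - mux) * (j - muy) * c
    homog <- homog + c / (1 + abs(i - j))
  }
  corr <- if (sigx * sigy == 0) 0 else corrNum / sqrt(sigx * sigy)
  if (convention == "printed") corr <- -corr
  c(energy = energy, entropy = entropy, inverseDifferenceMoment = idm,
    inertia = inertia, variance = varc, shade = shade, prominence = prom,
    correlation = corr, homogeneity = homog)
}

# Random small test volume with a dense mask.
randomGrayVolume <- function(maxDim = c(8L, 8L, 4L), levels = 4L,
                             maskProb = 0.85) {
  d <- c(sample(3:maxDim[1], 1), sample(3:maxDim[2], 1),
         sample(2:maxDim[3], 1))
  vox <- array(sample(0:(levels - 1), prod(d), replace = TRUE), d)
  mask <- array(runif(prod(d)) < maskProb, d)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  GrayVolume(vox, levels = levels, mask = mask)
}

# Brute-force interpolated precision at fixed recall levels and precision
# among the first n, per query, by explicit enumeration of the ranking.
oraclePR <- function(X, mal, w, recallLevels = c(0.25, 0.5, 0.75),
                     nTop = NULL) {
  grp <- ifelse(mal <= 2, "benign", "malignant")
  N <- nrow(X)
  ids <- rownames(X)
  precLev <- matrix(NA_real_, N, length(recallLevels))
  precN <- rep(NA_real_, N)
  for (q in 1:N) {
    d <- rep(NA_real_, N)
    for (o in 1:N) d[o] <- sqrt(sum(w * (X[q, ] - X[o, ])^2))
    others <- setdiff(1:N, q)
    ord <- others[order(d[others], ids[others])]
    rel <- grp[ord] == grp[q]
    prec <- cumsum(rel) / seq_along(rel)
    rec <- cumsum(rel) / sum(rel)
    for (k in seq_along(recallLevels))
      precLev[q, k] <- max(prec[rec >= recallLevels[k]])
    if (!is.null(nTop)) precN[q] <- mean(rel[1:nTop])
  }
  list(grp = grp, precLev = precLev, precN = precN)
}
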