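# Independent reference implementations used to cross-check the package.
# These deliberately use different algorithms from the implementation.

# point-in-convex-polygon by triangle-area decomposition: p is inside (or on
# the boundary of) the convex polygon iff the triangle fan areas sum to the
# polygon area
triangleAreaInQuad <- function(pt, corners) {
  triArea <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  n <- nrow(corners)
  polyA <- 0
  for (v in seq_len(n - 2))
    polyA <- polyA + triArea(corners[1, ], corners[v + 1, ], corners[v + 2, ])
  fanA <- 0
  for (v in seq_len(n))
    fanA <- fanA + triArea(pt, corners[v, ], corners[v %% n + 1, ])
  abs(fanA - polyA) <= 1e-9 * max(1, polyA)
}

# brute-force rasterization of a trapezoid prism by the area oracle
oracleRasterize <- function(corners, sliceRange, dims) {
  m <- array(FALSE, dims)
  plane <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(dims[1]))
    for (j in seq_len(dims[2]))
      plane[i, j] <- triangleAreaInQuad(c(i, j), corners)
  for (k in sliceRange[1]:sliceRange[2]) m[, , k] <- plane
  m
}

# random convex quadrilateral: four points on a random ellipse at sorted angles
randomConvexQuad <- function(dims, margin = 2) {
  repeat {
    ctr <- c(runif(1, margin + 3, dims[1] - margin - 3),
             runif(1, margin + 3, dims[2] - margin - 3))
    rad <- c(runif(1, 2, min(ctr[1], dims[1] - ctr[1]) - 0.5),
             runif(1, 2, min(ctr[2], dims[2] - ctr[2]) - 0.5))
    ang <- sort(runif(4, 0, 2 * pi))
    p <- cbind(ctr[1] + rad[1] * cos(ang), ctr[2] + rad[2] * sin(ang))
    area <- abs(sum(p[, 1] * p[c(2:4, 1), 2] - p[c(2:4, 1), 1] * p[, 2])) / 2
    if (min(diff(c(ang, ang[1] + 2 * pi))) > 0.3 && area > 4) return(p)
  }
}

# exhaustive best-first growth: at every step scan ALL voxels of the search
# region and admit the highest-valued voxel adjacent to the current region
# (no frontier bookkeeping; adjacency recomputed from scratch each step)
oracleGrow <- function(values, search, seed, n, connectivity = 26L) {
  d <- dim(values)
  offs <- connectivityOffsets(connectivity)
  region <- array(FALSE, d)
  region[seed[1], seed[2], seed[3]] <- TRUE
  while (sum(region) < n) {
    cand <- which(search & !region, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    adjacent <- logical(nrow(cand))
    regIdx <- which(region, arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      dd <- abs(sweep(regIdx, 2, cand[r, ]))
      for (q in seq_len(nrow(regIdx))) {
        delta <- regIdx[q, ] - cand[r, ]
        if (any(apply(offs, 1, function(o) all(o == delta)))) {
          adjacent[r] <- TRUE; break
        }
      }
    }
    cand <- cand[adjacent, , drop = FALSE]
    if (nrow(cand) == 0) break
    v <- values[cand]
    lin <- (cand[, 3] - 1) * d[1] * d[2] + (cand[, 2] - 1) * d[1] + cand[, 1]
    best <- order(-v, lin)[1]
    region[cand[best, 1], cand[best, 2], cand[best, 3]] <- TRUE
  }
  region
}

# connectivity check by BFS flood fill from the first voxel
isConnectedMask <- function(maskArr, connectivity = 26L) {
  idx <- which(maskArr, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(TRUE)
  d <- dim(maskArr)
  offs <- connectivityOffsets(connectivity)
  seen <- array(FALSE, d)
  queue <- matrix(idx[1, ], 1)
  seen[idx[1, , drop = FALSE]] <- TRUE
  while (nrow(queue)) {
    cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (o in seq_len(nrow(offs))) {
      nb <- cur + offs[o, ]
      if (any(nb < 1) || any(nb > d)) next
      if (maskArr[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
        seen[nb[1], nb[2], nb[3]] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
  }
  sum(seen) == nrow(idx)
}

# small phantom spec used across tests: same physics as the default, on a
# 64x64x32 grid (the striata and the 3-sigma blur margin fit comfortably)
smallSpec <- function(...) phantomSpec(shape = c(64L, 64L, 32L), ...)

# derive both VOIs and the SBR set for a phantom truth
analyzePhantom <- function(truth, params = extractionParams(), tb = TRUE) {
  img <- truth@volume
  voiT <- rasterizeTrapezoid(truth@suggestedVoiT, img)
  bg <- backgroundMask(truth@suggestedVoiBg, img)
  masks <- extractBilateral(img, voiT, params)
  tbR <- tbL <- NULL
  if (tb) {
    tbR <- buildTbVoi(maskCentroid(masks@right), img)
    tbL <- buildTbVoi(maskCentroid(masks@left), img)
  }
  list(img = img, voiT = voiT, bg = bg, masks = masks,
       sbr = sbrBilateral(img, masks, bg, tbR, tbL))
}
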