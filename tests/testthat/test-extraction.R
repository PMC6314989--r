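test_that("voxel budget conversion rounds to the nearest voxel, ties away from zero", {
  expect_identical(voxelCountForVolume(11.2, c(2.2, 2.2, 2.2)), 1052L)
  # exactly one voxel
  expect_identical(voxelCountForVolume(prod(c(2.2, 2.2, 2.2)) / 1000, c(2.2, 2.2, 2.2)), 1L)
  expect_identical(voxelCountForVolume(10.0, c(2.0, 2.0, 2.0)), 1250L)
  # x = 2.5 voxels rounds up (away from zero)
  expect_identical(voxelCountForVolume(0.0025, c(1, 1, 1)), 3L)
  expect_error(voxelCountForVolume(0, c(1, 1, 1)), "value error")
  expect_error(voxelCountForVolume(1, c(1, -1, 1)), "value error")
})

test_that("findPeak locates the maximum with the (k, j, i) tie rule", {
  d <- c(8, 8, 8)
  arr <- array(1, d); arr[4, 5, 6] <- 100
  img <- VolumeImage(arr, rep(1, 3))
  all8 <- MaskVolume(array(TRUE, d), rep(1, 3))
  expect_equal(findPeak(img, all8), c(4L, 5L, 6L))

  tie <- array(0, d); tie[2, 2, 2] <- 7; tie[5, 5, 5] <- 7
  expect_equal(findPeak(VolumeImage(tie, rep(1, 3)), all8), c(2L, 2L, 2L))

  # brute-force argmax property on random volumes
  set.seed(3)
  for (rep in 1:10) {
    v <- array(rnorm(prod(d)), d)
    got <- findPeak(VolumeImage(v, rep(1, 3)), all8)
    expect_equal(v[got[1], got[2], got[3]], max(v))
  }
  empty <- MaskVolume(array(FALSE, d), rep(1, 3))
  expect_error(findPeak(img, empty), "empty search")
})

test_that("growth of n = 1 is the seed; Chebyshev-ball values give the central block", {
  d <- c(5, 5, 5)
  cheb <- array(0, d)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    cheb[i, j, k] <- -max(abs(c(i, j, k) - 3))
  img <- VolumeImage(cheb, rep(1, 3))
  all5 <- MaskVolume(array(TRUE, d), rep(1, 3))

  one <- growFixedVolume(img, c(2, 4, 1), all5, 1)
  expect_equal(which(volumeData(one), arr.ind = TRUE)[1, ], c(dim1 = 2, dim2 = 4, dim3 = 1))

  m27 <- growFixedVolume(img, c(3, 3, 3), all5, 27, connectivity = 26)
  want <- array(FALSE, d); want[2:4, 2:4, 2:4] <- TRUE
  expect_identical(volumeData(m27), want)
})

test_that("growth cannot jump a zero gap wider than the connectivity reach", {
  d <- c(12, 5, 5)
  arr <- array(0, d)
  arr[1:3, 1:3, 1:3] <- 5      # blob A: 27 voxels
  arr[9:12, 1:3, 1:3] <- 9     # blob B, brighter, far away
  img <- VolumeImage(arr, rep(1, 3))
  search <- MaskVolume(arr > 0, rep(1, 3))
  within <- growFixedVolume(img, c(2, 2, 2), search, 20)
  idx <- which(volumeData(within), arr.ind = TRUE)
  expect_true(all(idx[, 1] <= 3))
  expect_error(growFixedVolume(img, c(2, 2, 2), search, 28),
               "shortfall error: only 27 voxels reachable.*28 requested")
})

test_that("greedy growth is nested and matches the exhaustive best-first oracle", {
  set.seed(21)
  for (rep in 1:12) {
    d <- c(sample(4:8, 1), sample(4:8, 1), sample(4:8, 1))
    v <- array(sample(seq_len(prod(d))), d)    # distinct values
    img <- VolumeImage(v, rep(1, 3))
    search <- MaskVolume(array(runif(prod(d)) < 0.85, d), rep(1, 3))
    idx <- which(volumeData(search), arr.ind = TRUE)
    seed <- idx[sample(nrow(idx), 1), ]
    conn <- sample(c(6L, 18L, 26L), 1)
    n <- sample(3:10, 1)
    got <- tryCatch(growFixedVolume(img, seed, search, n, conn),
                    error = function(e) NULL)
    if (is.null(got)) next                     # shortfall: oracle not comparable
    want <- oracleGrow(v, volumeData(search), seed, n, conn)
    expect_identical(volumeData(got), want)
    # monotone inclusion: growing further keeps the smaller region
    more <- tryCatch(growFixedVolume(img, seed, search, n + 3, conn),
                     error = function(e) NULL)
    if (!is.null(more))
      expect_true(all(volumeData(more)[volumeData(got)]))
  }
})

test_that("bilateral extraction yields disjoint connected masks of exact size", {
  truth <- generatePhantom(smallSpec(trueSbr = 2, psfFwhmMm = 0, noise = "none"))
  img <- truth@volume
  voiT <- rasterizeTrapezoid(truth@suggestedVoiT, img)
  masks <- extractBilateral(img, voiT)
  n <- voxelCountForVolume(11.2, voxelSpacing(img))
  expect_identical(masks@nVoxelsRequested, n)
  for (side in c("right", "left")) {
    m <- slot(masks, side)
    expect_equal(voxelCount(m), n)
    expect_true(isConnectedMask(volumeData(m)))
    pk <- masks@peaks[[side]]
    expect_true(volumeData(m)[pk[1], pk[2], pk[3]])
    expect_true(all(volumeData(voiT)[volumeData(m)]))
  }
  expect_false(any(volumeData(masks@right) & volumeData(masks@left)))
  # each side's mask contains its striatum's peak region
  expect_true(all(volumeData(masks@right)[volumeData(truth@rightMask)]))
  expect_true(all(volumeData(masks@left)[volumeData(truth@leftMask)]))
})

test_that("uniform image inside the VOI gives n-voxel masks and zero SBR downstream", {
  d <- c(40, 40, 20)
  img <- VolumeImage(array(7, d), rep(2.2, 3))
  voiT <- rasterizeTrapezoid(trapezoidVoi(rbind(c(5, 5), c(36, 5), c(36, 36), c(5, 36)),
                                          c(3, 18)), img)
  params <- extractionParams(standardVolumeMl = 2)   # 188 voxels per side
  masks <- extractBilateral(img, voiT, params)
  n <- voxelCountForVolume(2, rep(2.2, 3))
  expect_equal(voxelCount(masks@right), n)
  expect_equal(voxelCount(masks@left), n)
  bg <- backgroundMask(list(corner = c(2, 2, 1), extent = c(3, 3, 2)), img)
  res <- sbrCountBased(img, masks@right, bg, standardVolumeMl = 2)
  # uniform counts: striatal concentration equals background up to budget rounding
  expect_equal(sbrValue(res), n * prod(rep(2.2, 3)) / 1000 / 2 - 1, tolerance = 1e-12)
})

test_that("extraction errors are labelled with the failing side", {
  d <- c(10, 10, 10)
  img <- VolumeImage(array(1, d), rep(1, 3))
  tiny <- array(FALSE, d); tiny[1:2, 1:2, 1:2] <- TRUE
  expect_error(extractBilateral(img, MaskVolume(tiny, rep(1, 3)),
                                extractionParams(standardVolumeMl = 0.1)),
               "left side|right side")
})
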