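mkMask <- function(d, where, spacing) {
  m <- array(FALSE, d); m[where] <- TRUE
  MaskVolume(m, spacing)
}

test_that("uniform image gives SBR 0 up to budget rounding for both methods", {
  d <- c(20, 20, 20); sp <- rep(2, 3)          # voxel exactly 8 mm3
  img <- VolumeImage(array(5, d), sp)
  voi <- mkMask(d, cbind(3:12, 5, 5), sp)      # any VOI
  bg <- mkMask(d, cbind(15:18, 15, 15), sp)
  # Tossici-Bolt is exactly 0 on uniform images (Qvoi = Cr * Vvoi)
  expect_equal(sbrValue(sbrTossiciBolt(img, voi, bg, 11.2)), 0, tolerance = 1e-14)
  # count-based with a mask matching the budget: 1400 voxels x 8 mm3 = 11.2 mL
  n <- voxelCountForVolume(11.2, sp)
  expect_identical(n, 1400L)
  voiSt <- mkMask(d, which(array(seq_len(prod(d)), d) <= n), sp)
  expect_equal(sbrValue(sbrCountBased(img, voiSt, bg, 11.2)), 0, tolerance = 1e-14)
})

test_that("count-based SBR reproduces the hand-computed concentration ratio", {
  # 1052-voxel VOI totalling 2104 counts (mean 2/voxel), background 1/voxel,
  # 2.2 mm isotropic: sbr = 2 * 1052 * 0.010648 / 11.2 - 1
  d <- c(24, 24, 24); sp <- rep(2.2, 3)
  arr <- array(1, d)
  lin <- seq_len(1052L)
  arr[lin] <- 2
  img <- VolumeImage(arr, sp)
  voiSt <- mkMask(d, lin, sp)
  bg <- mkMask(d, which(array(seq_len(prod(d)), d) > 12000), sp)
  res <- sbrCountBased(img, voiSt, bg, 11.2)
  expect_equal(res@totalVoiCount, 2104)
  expect_equal(res@bgMeanPerVoxel, 1)
  expect_equal(res@bgConcPerMl, 1 / 0.010648, tolerance = 1e-12)
  expect_equal(sbrValue(res), 2 * 1052 * 0.010648 / 11.2 - 1, tolerance = 1e-12)
})

test_that("Tossici-Bolt reproduces the direct substitution case", {
  # Qvoi = 300, Cr = 10 /mL, Vvoi = 20 mL, Vs = 11.2 -> (30 - 20)/11.2
  d <- c(20, 20, 20); sp <- rep(2, 3)          # 0.008 mL voxels
  nLarge <- 2500L                              # 2500 x 0.008 = 20 mL
  arr <- array(10 * 0.008, d)                  # background 10 /mL everywhere
  arr[seq_len(nLarge)] <- 300 / nLarge         # large VOI totals 300
  img <- VolumeImage(arr, sp)
  voiLarge <- mkMask(d, seq_len(nLarge), sp)
  bg <- mkMask(d, which(array(seq_len(prod(d)), d) > 6000), sp)
  res <- sbrTossiciBolt(img, voiLarge, bg, 11.2)
  expect_equal(res@extras$Vvoi, 20, tolerance = 1e-12)
  expect_equal(res@extras$Cr, 10, tolerance = 1e-12)
  expect_equal(res@extras$R, 20 / 11.2, tolerance = 1e-12)
  expect_equal(sbrValue(res), (300 / 10 - 20) / 11.2, tolerance = 1e-12)
})

test_that("the two printed Tossici-Bolt forms are algebraically identical", {
  set.seed(9)
  worst <- 0
  for (rep in 1:25) {
    d <- c(16, 16, 12); sp <- runif(3, 1, 3)
    img <- VolumeImage(array(rexp(prod(d), 1 / 50), d), sp)
    lin <- sample(prod(d), 400)
    voi <- mkMask(d, lin[1:300], sp)
    bg <- mkMask(d, lin[301:400], sp)
    forms <- tbIdentity(img, voi, bg, 11.2)
    worst <- max(worst, abs(forms[1] - forms[2]) / max(1, abs(forms[1])))
  }
  expect_lt(worst, 1e-10)
})

test_that("both SBR methods are invariant under global count scaling", {
  truth <- generatePhantom(smallSpec(trueSbr = 1.5, seed = 3))
  res <- analyzePhantom(truth)
  scaled <- truth
  scaled@volume <- VolumeImage(volumeData(truth@volume) * 37.5,
                               voxelSpacing(truth@volume))
  res2 <- analyzePhantom(scaled)
  expect_equal(res2$sbr$count_based$right@sbr, res$sbr$count_based$right@sbr,
               tolerance = 1e-12)
  expect_equal(res2$sbr$tossici_bolt$left@sbr, res$sbr$tossici_bolt$left@sbr,
               tolerance = 1e-12)
})

test_that("adding a constant background shifts SBR by the closed form", {
  d <- c(20, 20, 20); sp <- rep(2.2, 3)
  set.seed(14)
  arr <- array(rexp(prod(d), 1 / 20) + 1, d)
  img <- VolumeImage(arr, sp)
  voiSt <- mkMask(d, seq_len(500), sp)
  bg <- mkMask(d, 6000 + seq_len(400), sp)
  b <- 13
  shifted <- VolumeImage(arr + b, sp)
  r0 <- sbrCountBased(img, voiSt, bg, 11.2)
  r1 <- sbrCountBased(shifted, voiSt, bg, 11.2)
  # closed form: concentrations gain b/Vs * nVox... expressed via totals
  voxMl <- prod(sp) / 1000
  cSt0 <- r0@totalVoiCount / 11.2; cBg0 <- r0@bgConcPerMl
  cSt1 <- cSt0 + b * 500 / 11.2;   cBg1 <- cBg0 + b / voxMl
  expect_equal(sbrValue(r1), (cSt1 - cBg1) / cBg1, tolerance = 1e-12)
})

test_that("enlarging the TB VOI into homogeneous background leaves SBR unchanged", {
  truth <- generatePhantom(smallSpec(trueSbr = 2, psfFwhmMm = 0, noise = "none"))
  res <- analyzePhantom(truth)
  img <- res$img
  small <- buildTbVoi(maskCentroid(res$masks@right), img, radiiMm = c(22, 26),
                      thicknessMm = 35.2)
  big <- buildTbVoi(maskCentroid(res$masks@right), img, radiiMm = c(26, 36),
                    thicknessMm = 44)
  expect_true(all(volumeData(big)[volumeData(small)]))
  s1 <- sbrValue(sbrTossiciBolt(img, small, res$bg, 11.2))
  s2 <- sbrValue(sbrTossiciBolt(img, big, res$bg, 11.2))
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("TB cylinder rasterization matches brute-force centre inclusion", {
  d <- c(40, 40, 30); sp <- rep(2.2, 3)
  ref <- VolumeImage(array(0, d), sp)
  ctr <- c(20, 21, 15); radii <- c(25, 30); thick <- 44
  m <- buildTbVoi(ctr, ref, radiiMm = radii, thicknessMm = thick)
  cnt <- 0L
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    inPlane <- ((i - ctr[1]) * sp[1] / radii[1])^2 +
               ((j - ctr[2]) * sp[2] / radii[2])^2 <= 1
    inAxial <- abs(k - ctr[3]) * sp[3] <= thick / 2
    cnt <- cnt + (inPlane && inAxial)
  }
  expect_equal(voxelCount(m), cnt)

  # one-slice disc at minimal thickness
  disc <- buildTbVoi(ctr, ref, radiiMm = c(10, 10), thicknessMm = 2.2)
  expect_equal(length(unique(which(volumeData(disc), arr.ind = TRUE)[, 3])), 1L)

  expect_error(buildTbVoi(c(200, 20, 15), ref), "geometry error")
  expect_error(buildTbVoi(c(4, 20, 15), ref, radiiMm = c(25, 30)), "geometry error")
})

test_that("SBR preconditions are enforced", {
  d <- c(12, 12, 12); sp <- rep(2, 3)
  img <- VolumeImage(array(1, d), sp)
  voi <- mkMask(d, seq_len(50), sp)
  overlap <- mkMask(d, 26:75, sp)
  expect_error(sbrCountBased(img, voi, overlap), "overlaps")
  zeroBg <- VolumeImage(array(0, d), sp)
  bg <- mkMask(d, 1000 + seq_len(50), sp)
  expect_error(sbrCountBased(zeroBg, voi, bg), "background mean")
  wrong <- mkMask(c(10, 10, 10), 1:5, sp)
  expect_error(sbrCountBased(img, wrong, bg), "alignment error")
})
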