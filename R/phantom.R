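# mm coordinate of a voxel centre along one axis: (index - 1) * spacing
axisCoords <- function(n, sp) (seq_len(n) - 1) * sp

#' Construct a phantom specification
#'
#' The default geometry emulates a reconstructed DaT-SPECT study: a
#' 128x128x64 grid at 2.2 mm isotropic spacing, two ellipsoidal striata of
#' semi-axes (10, 20, 13.37) mm — continuous volume 11.200 mL per side,
#' discretizing to about 1052 voxels — centred 25 mm either side of the
#' grid midline, a uniform nonspecific background of 30 counts/voxel, a
#' 10 mm FWHM Gaussian PSF, and Poisson noise applied after the blur.
#'
#' @param shape integer(3) grid dimensions.
#' @param spacing numeric(3) voxel size in mm.
#' @param trueSbr ground-truth SBR, length 1 (both sides) or named
#'   `c(right=, left=)`.
#' @param centresMm optional 2x3 matrix of striatal centres in mm (rows
#'   right, left); default: grid centre offset -25 / +25 mm along axis 1.
#' @param semiAxesMm per-side ellipsoid semi-axes in mm: numeric(3) shared
#'   by both sides or a 2x3 matrix.
#' @param backgroundLevel counts/voxel (> 0).
#' @param psfFwhmMm Gaussian PSF FWHM in mm (0 disables blurring).
#' @param noise `"none"` or `"poisson"`.
#' @param countScale multiplier applied before the Poisson draw.
#' @param seed RNG seed for the noise draw.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(128L, 128L, 64L), spacing = rep(2.2, 3),
                        trueSbr = 3, centresMm = NULL,
                        semiAxesMm = c(10, 20, 13.37), backgroundLevel = 30,
                        psfFwhmMm = 10, noise = "poisson", countScale = 1,
                        seed = 1L) {
  shape <- as.integer(shape)
  if (length(trueSbr) == 1L) trueSbr <- c(right = trueSbr, left = trueSbr)
  if (is.null(names(trueSbr))) names(trueSbr) <- c("right", "left")
  if (is.null(centresMm)) {
    ctr <- (shape - 1) * spacing / 2
    centresMm <- rbind(right = ctr + c(-25, 0, 0), left = ctr + c(25, 0, 0))
  }
  if (!is.matrix(semiAxesMm)) semiAxesMm <- rbind(right = semiAxesMm, left = semiAxesMm)
  new("PhantomSpec", shape = shape, spacing = as.numeric(spacing),
      centresMm = centresMm, semiAxesMm = semiAxesMm,
      trueSbr = trueSbr[c("right", "left")],
      backgroundLevel = as.numeric(backgroundLevel),
      psfFwhmMm = as.numeric(psfFwhmMm), noise = noise,
      countScale = as.numeric(countScale), seed = as.integer(seed))
}

ellipsoidMask <- function(shape, spacing, centreMm, semiAxesMm) {
  x <- (axisCoords(shape[1L], spacing[1L]) - centreMm[1L]) / semiAxesMm[1L]
  y <- (axisCoords(shape[2L], spacing[2L]) - centreMm[2L]) / semiAxesMm[2L]
  z <- (axisCoords(shape[3L], spacing[3L]) - centreMm[3L]) / semiAxesMm[3L]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

# separable Gaussian blur; kernel truncated at 4 sigma. Rows of the band
# matrix are renormalized at the borders so a constant field is preserved
# exactly: the uniform nonspecific background does not darken at the grid
# edge, and sources >= 3 sigma from the edge conserve their total counts.
gaussianBlur3d <- function(arr, sigmaVox) {
  blurAxis <- function(a, sigma) {
    if (sigma <= 0) return(a)
    d <- dim(a)
    r <- max(1L, ceiling(4 * sigma))
    k <- dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    n <- d[1L]
    K <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n)
      src <- idx + o
      ok <- src >= 1L & src <= n
      K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[o + r + 1L]
    }
    K <- K / rowSums(K)
    array(K %*% matrix(a, n, prod(d[-1L])), d)
  }
  arr <- blurAxis(arr, sigmaVox[1L])
  arr <- aperm(blurAxis(aperm(arr, c(2, 1, 3)), sigmaVox[2L]), c(2, 1, 3))
  aperm(blurAxis(aperm(arr, c(3, 2, 1)), sigmaVox[3L]), c(3, 2, 1))
}

withPhantomSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic DaT-SPECT phantom
#'
#' Pipeline: paint ellipsoidal striata at activity
#' `backgroundLevel * (1 + trueSbr)` over a uniform background, apply an
#' isotropic Gaussian PSF (`sigma = FWHM / 2.3548` mm, converted per axis
#' to voxels), multiply by `countScale`, then draw Poisson counts if
#' requested. Deterministic given the spec's seed. The ground-truth masks
#' are the pre-blur ellipsoid supports.
#'
#' Also returned: a suggested trapezoid search VOI covering both striata
#' and a suggested occipital-style background box placed well posterior of
#' the striata (beyond 3 sigma of the PSF).
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomTruth-class].
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@shape
  act <- array(spec@backgroundLevel, d)
  masks <- list()
  for (s in 1:2) {
    side <- c("right", "left")[s]
    m <- ellipsoidMask(d, spec@spacing, spec@centresMm[s, ], spec@semiAxesMm[s, ])
    act[m] <- spec@backgroundLevel * (1 + spec@trueSbr[[side]])
    masks[[side]] <- MaskVolume(m, spec@spacing)
  }
  if (spec@psfFwhmMm > 0)
    act <- gaussianBlur3d(act, spec@psfFwhmMm / 2.354820045 / spec@spacing)
  act <- act * spec@countScale
  if (spec@noise == "poisson") {
    vals <- withPhantomSeed(spec@seed, rpois(length(act), as.vector(act)))
    act <- array(as.double(vals), d)
  }
  vol <- VolumeImage(act, spec@spacing, meta = list(phantom = TRUE, seed = spec@seed))

  ctrVox <- colMeans(spec@centresMm) / spec@spacing + 1     # midpoint, voxels
  halfI <- (abs(spec@centresMm[1, 1] - spec@centresMm[2, 1]) / 2 +
            max(spec@semiAxesMm[, 1]) + 8) / spec@spacing[1L]
  halfJ <- (max(spec@semiAxesMm[, 2]) + 8) / spec@spacing[2L]
  halfK <- ceiling((max(spec@semiAxesMm[, 3]) + 5) / spec@spacing[3L])
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  i0 <- clamp(ctrVox[1L] - halfI, 1, d[1L]); i1 <- clamp(ctrVox[1L] + halfI, 1, d[1L])
  j0 <- clamp(ctrVox[2L] - halfJ, 1, d[2L]); j1 <- clamp(ctrVox[2L] + halfJ, 1, d[2L])
  k0 <- as.integer(clamp(round(ctrVox[3L]) - halfK, 1, d[3L]))
  k1 <- as.integer(clamp(round(ctrVox[3L]) + halfK, 1, d[3L]))
  voiT <- trapezoidVoi(rbind(c(i0, j0), c(i1, j0), c(i1, j1), c(i0, j1)),
                       c(k0, k1))

  # background box: posterior (low j), centred in i at striatum slice level
  bgJ <- clamp(round((min(spec@centresMm[, 2]) - 48) / spec@spacing[2L]) + 1L,
               1, d[2L])
  bgCorner <- c(as.integer(round(ctrVox[1L])) - 7L, as.integer(bgJ) - 2L,
                as.integer(round(ctrVox[3L])) - 1L)
  bgSpec <- list(corner = bgCorner, extent = c(15L, 5L, 2L))

  new("PhantomTruth", volume = vol, rightMask = masks$right,
      leftMask = masks$left, trueSbr = spec@trueSbr, suggestedVoiT = voiT,
      suggestedVoiBg = bgSpec, spec = spec)
}

#' Generate a labelled cohort of phantoms
#'
#' Ground-truth SBR values are drawn uniformly from each group's interval;
#' per-subject noise seeds are derived deterministically from the master
#' seed. `rightScale` below 1 produces lateralized ("dot pattern"-like)
#' cases with reduced right-side uptake.
#'
#' @param nAbnormal,nNormal subjects per group (>= 1).
#' @param sbrRanges list with numeric(2) elements `abnormal` and `normal`.
#' @param baseSpec template [PhantomSpec-class]; its `trueSbr` and `seed`
#'   are overridden per subject.
#' @param seed master seed.
#' @param rightScale multiplier on the right side's true SBR (default 1).
#' @return list with `truths` (list of [PhantomTruth-class]) and a
#'   data.frame `labels` (subject, group, trueSbrRight, trueSbrLeft).
#' @export
generateCohort <- function(nAbnormal, nNormal,
                           sbrRanges = list(abnormal = c(0.5, 1.5),
                                            normal = c(2.5, 3.5)),
                           baseSpec = phantomSpec(), seed = 1L,
                           rightScale = 1) {
  stopifnot(nAbnormal >= 1, nNormal >= 1)
  for (g in c("abnormal", "normal")) {
    rg <- sbrRanges[[g]]
    if (is.null(rg) || length(rg) != 2L || rg[2L] < rg[1L])
      stop(sprintf("value error: empty or invalid range for group '%s'", g),
           call. = FALSE)
  }
  groups <- c(rep("abnormal", nAbnormal), rep("normal", nNormal))
  n <- length(groups)
  draws <- withPhantomSeed(seed, list(sbr = runif(n), seeds = sample.int(2^31 - 1, n)))
  truths <- vector("list", n)
  lab <- data.frame(subject = sprintf("S%03d", seq_len(n)), group = groups,
                    trueSbrRight = NA_real_, trueSbrLeft = NA_real_,
                    stringsAsFactors = FALSE)
  for (s in seq_len(n)) {
    rg <- sbrRanges[[groups[s]]]
    base <- rg[1L] + draws$sbr[s] * (rg[2L] - rg[1L])
    sp <- baseSpec
    sp@trueSbr <- c(right = base * rightScale, left = base)
    sp@seed <- draws$seeds[s]
    truths[[s]] <- generatePhantom(sp)
    lab$trueSbrRight[s] <- sp@trueSbr[["right"]]
    lab$trueSbrLeft[s] <- sp@trueSbr[["left"]]
  }
  list(truths = truths, labels = lab)
}
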