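# Registration, error/SSIM maps, medians, pSNR, noise-vs-direction.

test_that("registration recovers imposed integer and subpixel shifts", {
  sim <- smallSim(noiseSigma = 0, phaseOrder = 0L)
  v <- sim$vols[, , , 1]
  expect_error(registerShift(array(1, dim(v)), v), "flat")
  # zero shift
  r0 <- registerShift(v, v)
  expect_lt(max(abs(r0$shift)), 1e-3)
  # imposed shifts recovered within 0.05 px (2.0, 0.6, 0.3 px working range)
  for (s in list(c(2, -1, 0), c(0, 0.6, 0), c(0.3, 0, 0))) {
    vs <- Re(klrcs:::shiftImage(v, s))
    r <- registerShift(vs, v)
    expect_lt(max(abs(r$shift - s)), 0.05)
    # registered volume close to the reference (taking the real part of a
    # subpixel-shifted real image is itself slightly lossy)
    expect_lt(klrcs:::relDiff(Re(r$registered), v), 0.1)
  }
})

test_that("percent-error maps are exact, floored and scale-invariant", {
  d <- c(6, 6, 4)
  ref <- array(2, d); test <- array(2.1, d)
  mask <- array(TRUE, d)
  e <- errorMap(test, ref, mask)
  expect_equal(as.vector(e), rep(5, prod(d)), tolerance = 1e-12)
  # identity
  expect_true(all(errorMap(ref, ref, mask) == 0))
  # homogeneity: scaling both maps leaves the error untouched
  e2 <- errorMap(3.7 * test, 3.7 * ref, mask)
  expect_equal(e2, e, tolerance = 1e-12)
  # outside-mask voxels are excluded
  mask2 <- mask; mask2[1, 1, 1] <- FALSE
  e3 <- errorMap(test, ref, mask2)
  expect_true(is.na(e3[1, 1, 1]))
  expect_error(errorMap(test, ref, array(FALSE, d)), "empty mask")
})

test_that("SSIM is 1 on self, symmetric for equal-range inputs, noise-degraded", {
  sim <- smallSim(noiseSigma = 0, phaseOrder = 0L)
  x <- sim$vols[, , , 5]                  # a weighted volume (non-constant)
  mask <- sim$mask
  s <- ssimMap(x, x, mask)
  expect_equal(max(abs(s[mask] - 1)), 0, tolerance = 1e-9)
  # symmetry (both orders) when the dynamic ranges agree: evaluate over the
  # full volume so both orders see the same masked range
  y <- x[dim(x)[1]:1, , ]                 # mirrored copy: same value range
  full <- array(TRUE, dim(x))
  expect_equal(ssimMap(x, y, full), ssimMap(y, x, full), tolerance = 1e-10)
  # seeded noise strictly lowers the median SSIM
  set.seed(31)
  xn <- x + array(rnorm(length(x), sd = 0.05 * max(x)), dim(x))
  expect_lt(median(ssimMap(xn, x, mask)[mask]), 1)
  expect_error(ssimMap(x, array(1, dim(x)), mask), "dynamic range")
})

test_that("median metrics summarise only the masked voxels", {
  d <- c(3, 1, 1)
  e <- array(c(1, 2, 3), d); s <- array(c(0.9, 0.8, 0.7), d)
  mask <- array(TRUE, d)
  mm <- medianMetrics(e, s, mask)
  expect_identical(mm$medianError, 2)
  expect_identical(mm$medianSSIM, 0.8)
  # identical maps give (0, 1)
  z <- array(0, d); o <- array(1, d)
  mm0 <- medianMetrics(z, o, mask)
  expect_identical(c(mm0$medianError, mm0$medianSSIM), c(0, 1))
  # values outside the mask are ignored
  e2 <- e; e2[3, 1, 1] <- 1e6
  mask2 <- mask; mask2[3, 1, 1] <- FALSE
  expect_identical(medianMetrics(e2, s, mask2)$medianError, 1.5)
})

test_that("pSNR matches its construction and responds to noise and scale", {
  shape <- c(32, 32, 16)
  ph <- makePhantom(shape)
  mask <- brainMask(ph)
  bg <- !mask
  sc <- makeScheme(1, 8, 1000)
  co1 <- new("CoilProfiles", profiles = array(1 + 0i, c(shape, 1)))
  vols <- dwiSignal(ph, sc)
  mkVol <- function(sig, seed = 41) {
    ks <- simulateKspace(vols, co1, sc, phaseOrder = 0, noiseSigma = sig,
                         seed = seed)
    Mod(klrcs:::ifftc(kspaceData(ks)[, , , 1, 1]))
  }
  v <- mkVol(0.01)
  # peak ~ 1, background std ~ 0.01 * sqrt(2 - pi/2) (Rayleigh magnitude)
  expect_equal(psnr(v, mask, bg), 1 / (0.01 * sqrt(2 - pi / 2)),
               tolerance = 0.1)
  # scale invariance
  expect_equal(psnr(2 * v, mask, bg), psnr(v, mask, bg), tolerance = 1e-12)
  # strictly decreasing in noise
  ps <- vapply(c(0.005, 0.01, 0.02), function(s) psnr(mkVol(s), mask, bg), 0)
  expect_true(all(diff(ps) < 0))
  expect_error(psnr(v, mask, mask), "disjoint")
})

test_that("background noise level is independent of the diffusion direction", {
  sim <- smallSim(noiseSigma = 0.01, phaseOrder = 0L, seed = 51)
  rec <- zeroFillRecon(sim$ks)
  bg <- !sim$mask
  nv <- noiseVsDirection(rec, bg, sim$scheme)
  expect_lt(nv$cv, 0.1)
  # sigma = 0 gives all-zero stds
  sim0 <- smallSim(noiseSigma = 0, phaseOrder = 0L, seed = 51)
  nv0 <- noiseVsDirection(zeroFillRecon(sim0$ks), bg, sim0$scheme)
  expect_true(all(nv0$std < 1e-12))
  # doubling sigma doubles every per-volume std within 5%
  sim2 <- smallSim(noiseSigma = 0.02, phaseOrder = 0L, seed = 51)
  nv2 <- noiseVsDirection(zeroFillRecon(sim2$ks), bg, sim2$scheme)
  expect_true(all(abs(nv2$std / nv$std - 2) < 0.1))
})
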