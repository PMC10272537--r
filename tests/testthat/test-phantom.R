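# Synthetic phantom, forward signal model and k-space simulation.

test_that("phantom regions carry the intended tensors", {
  ph <- makePhantom(c(24, 24, 12))
  gt <- phantomScalarMaps(ph)
  lab <- ph@labels
  # isotropic parenchyma: FA 0, MD = d
  expect_equal(max(faMap(gt)[lab == 1L]), 0, tolerance = 1e-10)
  expect_equal(mean(mdMap(gt)[lab == 1L]), 0.7e-3, tolerance = 1e-12)
  # prolate tract: MD is the eigenvalue mean
  expect_true(any(lab > 3L))
  expect_equal(mean(mdMap(gt)[lab > 3L]), mean(c(1.7e-3, 0.2e-3, 0.2e-3)),
               tolerance = 1e-12)
  expect_equal(mean(faMap(gt)[lab > 3L]), 0.8703883, tolerance = 1e-6)
  # S0 vanishes outside the mask
  expect_true(all(ph@S0[!brainMask(ph)] == 0))
})

test_that("diffusion signal follows the mono-exponential tensor model", {
  ph <- makePhantom(c(16, 16, 8), nTracts = 0L)
  sc <- makeScheme(1, 8, 1000)
  vols <- dwiSignal(ph, sc)
  # b0 returns S0
  expect_equal(vols[, , , 1], ph@S0, tolerance = 1e-15)
  # isotropic: S/S0 = exp(-b d) for every direction
  msk <- ph@labels == 1L
  for (v in c(2, 5, 9))
    expect_equal(mean(vols[, , , v][msk]), exp(-1000 * 0.7e-3),
                 tolerance = 1e-12)
  expect_true(all(vols >= 0 & vols <= max(ph@S0)))
  # closed form for an axis-aligned anisotropic tensor
  D <- diag(c(2e-3, 2e-4, 2e-4))
  g <- c(1, 0, 0)
  expect_equal(exp(-1000 * drop(g %*% D %*% g)), exp(-2), tolerance = 1e-12)
})

test_that("coil profiles are smooth with positive sum of squares", {
  shape <- c(32, 32, 16)
  for (seed in c(0, 3, 9)) {
    co <- makeCoilProfiles(shape, 4, seed = seed)
    prof <- coilArray(co)
    sos <- apply(Mod(prof)^2, 1:3, sum)
    expect_true(all(sos > 0))
    # smoothness: voxel-to-voxel change small relative to the field scale
    for (c in 1:4) {
      p <- prof[, , , c]
      dmax <- max(Mod(p[-1, , ] - p[-shape[1], , ]))
      expect_lt(dmax, 0.2 * max(Mod(p)))
    }
  }
  expect_identical(coilArray(makeCoilProfiles(shape, 4, seed = 3)),
                   coilArray(makeCoilProfiles(shape, 4, seed = 3)))
})

test_that("noiseless simulation round-trips and respects Hermitian symmetry", {
  sim <- smallSim(noiseSigma = 0, phaseOrder = 0L)
  shape <- dim(sim$vols)[1:3]
  co1 <- new("CoilProfiles",
             profiles = array(1 + 0i, c(shape, 1)))
  ks <- simulateKspace(sim$vols, co1, sim$scheme, phaseOrder = 0,
                       noiseSigma = 0, seed = 1)
  rec <- zeroFillRecon(ks)
  expect_lt(max(abs(rec - sim$vols)), 1e-10)
  # Parseval under the orthonormal convention (factor 1)
  k1 <- kspaceData(ks)[, , , 1, 1]
  expect_equal(sum(Mod(k1)^2), sum(sim$vols[, , , 1]^2), tolerance = 1e-10)
  # real object => conjugate-symmetric k-space (even-length axes: drop the
  # unmatched -n/2 row along each axis)
  X <- k1
  d <- dim(X)
  idx <- lapply(d, function(n) 2:n)
  Xs <- X[idx[[1]], idx[[2]], idx[[3]]]
  Xr <- Conj(X[rev(idx[[1]]), rev(idx[[2]]), rev(idx[[3]])])
  herm0 <- max(Mod(Xs - Xr)) / max(Mod(X))
  expect_lt(herm0, 1e-10)
  # smooth object phase breaks the symmetry
  ks2 <- simulateKspace(sim$vols, co1, sim$scheme, phaseOrder = 2,
                        noiseSigma = 0, seed = 1)
  X2 <- kspaceData(ks2)[, , , 1, 1]
  X2s <- X2[idx[[1]], idx[[2]], idx[[3]]]
  X2r <- Conj(X2[rev(idx[[1]]), rev(idx[[2]]), rev(idx[[3]])])
  expect_gt(max(Mod(X2s - X2r)) / max(Mod(X2)), 1e3 * herm0)
})

test_that("image-domain noise level matches the simulated k-space sigma", {
  shape <- c(32, 32, 16)
  ph <- makePhantom(shape)
  sc <- makeScheme(1, 8, 1000)
  co1 <- new("CoilProfiles", profiles = array(1 + 0i, c(shape, 1)))
  sigma <- 0.01
  ks <- simulateKspace(dwiSignal(ph, sc), co1, sc, phaseOrder = 0,
                       noiseSigma = sigma, seed = 4)
  img <- klrcs:::ifftc(kspaceData(ks)[, , , 1, 1])
  bg <- !brainMask(ph)
  # unitary FFT preserves iid complex Gaussian noise componentwise
  expect_equal(sd(Re(img[bg])), sigma, tolerance = 0.05)
  expect_equal(sd(Im(img[bg])), sigma, tolerance = 0.05)
})

test_that("drift shifts volumes linearly and preserves k-space magnitudes", {
  sim <- smallSim(noiseSigma = 0, phaseOrder = 0L)
  ks <- sim$ks
  ksd <- applyDrift(ks, totalShiftPx = 0.6, axis = 2L)
  expect_equal(Mod(kspaceData(ksd)), Mod(kspaceData(ks)), tolerance = 1e-12)
  # zero drift is the identity
  expect_identical(kspaceData(applyDrift(ks, 0)), kspaceData(ks))
  # integer total shift: last volume equals a circular shift of the input
  ks2 <- applyDrift(ks, totalShiftPx = 2, axis = 2L)
  nV <- nVolumes(ks2)
  last <- klrcs:::ifftc(kspaceData(ks2)[, , , 1, nV])
  orig <- klrcs:::ifftc(kspaceData(ks)[, , , 1, nV])
  expect_lt(max(Mod(last - klrcs:::circShift(orig, c(0, 2, 0)))), 1e-10)
  # registration recovers the imposed subpixel shift of the last volume
  r <- registerShift(Mod(last0 <- klrcs:::ifftc(kspaceData(applyDrift(ks, 0.6))[, , , 1, nV])),
                     Mod(orig))
  expect_lt(max(abs(r$shift - c(0, 0.6, 0))), 0.05)
  # per-volume estimated shifts grow linearly with volume index (complex
  # registration: the phase-ramp shift model is exact for complex images)
  ests <- vapply(seq_len(nV), function(v) {
    mv <- klrcs:::ifftc(kspaceData(ksd)[, , , 1, v])
    rf <- klrcs:::ifftc(kspaceData(ks)[, , , 1, v])
    registerShift(mv, rf)$shift[2]
  }, 0)
  fitLm <- stats::lm(ests ~ seq_len(nV))
  expect_gt(summary(fitLm)$r.squared, 0.99)
})

test_that("retrospective undersampling zeroes unsampled points and is idempotent", {
  sim <- smallSim()
  ms <- buildMaskSet(sim$grid, sim$scheme, af = 2, fsB0 = TRUE, seed = 2)
  us <- retrospectiveUndersample(sim$ks, ms)
  m <- maskArray(ms)
  d <- dim(kspaceData(us))
  v <- nVolumes(sim$ks)              # a diffusion volume
  kv <- kspaceData(us)[, , , 1, v]
  mv <- array(rep(m[, , v], each = d[1]), d[1:3])
  expect_true(all(kv[mv == 0] == 0))
  expect_equal(kv[mv == 1], kspaceData(sim$ks)[, , , 1, v][mv == 1])
  # sampled fraction equals 1/AF_diff
  expect_equal(mean(Mod(kv) > 0), sum(m[, , v]) / prod(d[2:3]),
               tolerance = 1e-3)
  # idempotent
  us2 <- retrospectiveUndersample(us, ms)
  expect_identical(kspaceData(us2), kspaceData(us))
  # all-ones masks are the identity
  msFull <- buildMaskSet(sim$grid, sim$scheme, af = 1, seed = 2)
  expect_identical(kspaceData(retrospectiveUndersample(sim$ks, msFull)),
                   kspaceData(sim$ks))
})
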