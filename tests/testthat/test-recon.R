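# KLR reconstruction building blocks and pipeline identities.

test_that("low-resolution prior is confined to the k-space centre", {
  sim <- smallSim(noiseSigma = 0.004)
  ms <- buildMaskSet(sim$grid, sim$scheme, af = 2, fsB0 = TRUE, seed = 3)
  us <- retrospectiveUndersample(sim$ks, ms)
  prior <- extractLowRes(us, maskSet = ms)
  low <- lowresImages(prior)
  # re-FFT of the low-res images vanishes outside the centre block
  g <- sim$grid
  h <- g@centerHalfwidths
  cb <- outer(abs(klrcs:::centeredIndex(g@nPE1)) <= h[1],
              abs(klrcs:::centeredIndex(g@nPE2)) <= h[2], `&`)
  k <- klrcs:::fftc(low[, , , 1, 1])
  outside3 <- array(rep(!cb, each = dim(k)[1]), dim(k))
  expect_lt(max(Mod(k[outside3])) / max(Mod(k)), 1e-12)
  # phases live in (-pi, pi]
  expect_true(all(phaseMaps(prior) > -pi - 1e-12 &
                  phaseMaps(prior) <= pi + 1e-12))
  # full-plane centre reproduces the zero-filled reconstruction
  gFull <- samplingGrid(g@nRead, g@nPE1, g@nPE2,
                        centerHalfwidths = c(g@nPE1 %/% 2 - 1, g@nPE2 %/% 2 - 1))
  ksFull <- new("MultiCoilKSpace", data = kspaceData(sim$ks), grid = gFull,
                scheme = sim$scheme, noiseSigma = 0.004, seed = 11L)
  priorFull <- extractLowRes(ksFull,
                             centerHalfwidths = c(g@nPE1 %/% 2 - 1,
                                                  g@nPE2 %/% 2 - 1))
  # the widest legal centre misses only the unmatched edge rows of k-space
  full <- klrcs:::ifftc(kspaceData(sim$ks)[, , , 1, 1])
  expect_lt(klrcs:::relDiff(lowresImages(priorFull)[, , , 1, 1], full), 0.2)
  # a centre not fully sampled errors
  expect_error(extractLowRes(us, centerHalfwidths = c(g@nPE1 %/% 2 - 1,
                                                      g@nPE2 %/% 2 - 1),
                             maskSet = ms),
               "not fully sampled")
  # constant image: any centre containing DC reproduces it exactly
  d <- dim(kspaceData(sim$ks))
  const <- array(1, d[1:3])
  scOne <- new("DiffusionScheme", bvals = 0, bvecs = matrix(0, 3, 1))
  ksC <- new("MultiCoilKSpace",
             data = array(klrcs:::fftc(const), c(d[1:3], 1, 1)),
             grid = g, scheme = scOne, noiseSigma = 0, seed = 1L)
  priorC <- extractLowRes(ksC)
  expect_lt(max(Mod(lowresImages(priorC)[, , , 1, 1] - const)), 1e-12)
})

test_that("phase reattachment and data consistency obey their contracts", {
  sim <- smallSim(noiseSigma = 0.004)
  ms <- buildMaskSet(sim$grid, sim$scheme, af = 2, fsB0 = TRUE, seed = 3)
  us <- retrospectiveUndersample(sim$ks, ms)
  prior <- extractLowRes(us, maskSet = ms)
  mags <- Mod(lowresImages(prior))
  out <- reattachPhase(mags, prior)
  expect_equal(Mod(out), mags, tolerance = 1e-14)
  pos <- mags > 1e-9
  expect_lt(max(abs(Arg(out)[pos] - phaseMaps(prior)[pos])), 1e-10)
  # zero phase returns the magnitudes untouched
  prior0 <- prior
  prior0@phaseMaps[] <- 0
  expect_equal(Re(reattachPhase(mags, prior0)), mags, tolerance = 1e-14)
  # data consistency: sampled points bitwise from acquired, others kept
  est <- kspaceData(us) * 0
  dcK <- dataConsistency(est, kspaceData(us), ms)
  expect_identical(dcK, kspaceData(us))       # zero estimate -> acquired
  est2 <- kspaceData(us) + (0.3 + 0.1i)
  dcK2 <- dataConsistency(est2, kspaceData(us), ms)
  m <- maskArray(ms)
  d <- dim(est2)
  v <- d[5]
  sel <- array(rep(m[, , v] == 1L, each = d[1]), d[1:3])
  expect_identical(dcK2[, , , 1, v][sel], kspaceData(us)[, , , 1, v][sel])
  expect_identical(dcK2[, , , 1, v][!sel], est2[, , , 1, v][!sel])
  # all-ones masks: estimate fully replaced
  msFull <- buildMaskSet(sim$grid, sim$scheme, af = 1, seed = 3)
  expect_identical(dataConsistency(est2, kspaceData(sim$ks), msFull),
                   kspaceData(sim$ks))
  expect_error(dataConsistency(est2[, , , 1, , drop = FALSE],
                               kspaceData(us), ms), "shape")
})

test_that("ratio sensitivity maps are normalised and recover true profiles", {
  sim <- smallSim(noiseSigma = 0, phaseOrder = 2L)
  d <- dim(kspaceData(sim$ks))
  chan <- array(complex(real = 0), d[1:4])
  for (c in seq_len(d[4]))
    chan[, , , c] <- klrcs:::ifftc(kspaceData(sim$ks)[, , , c, 1])
  maps <- ratioSensitivities(chan)
  sos2 <- apply(Mod(maps)^2, 1:3, sum)
  inObj <- sim$mask
  expect_lt(max(abs(sos2[inObj] - 1)), 1e-12)
  # maps proportional to the true profiles up to a unit-modulus field:
  # coil ratios must match the true profile ratios
  prof <- coilArray(sim$coils)
  ratioEst <- maps[, , , 2] / maps[, , , 1]
  ratioTrue <- prof[, , , 2] / prof[, , , 1]
  expect_lt(median(Mod(ratioEst - ratioTrue)[inObj]), 1e-8)
  # single coil: |map| = 1 on object
  m1 <- ratioSensitivities(chan[, , , 1, drop = FALSE])
  expect_lt(max(abs(Mod(m1[, , , 1])[inObj] - 1)), 1e-12)
})

test_that("channel combination reduces to known identities", {
  sim <- smallSim(noiseSigma = 0, phaseOrder = 0L)
  shape <- dim(sim$vols)[1:3]
  co1 <- new("CoilProfiles", profiles = array(1 + 0i, c(shape, 1)))
  ks <- simulateKspace(sim$vols, co1, sim$scheme, phaseOrder = 0,
                       noiseSigma = 0, seed = 1)
  d <- dim(kspaceData(ks))
  chan <- array(complex(real = 0), d)
  for (v in seq_len(d[5]))
    chan[, , , 1, v] <- klrcs:::ifftc(kspaceData(ks)[, , , 1, v])
  maps <- array(1 + 0i, c(shape, 1))
  comb <- combineChannels(chan, maps, "matched")
  expect_lt(max(Mod(comb - sim$vols)), 1e-10)
  # SoS is invariant to per-coil unit-modulus fields
  sim3 <- smallSim(noiseSigma = 0, phaseOrder = 2L)
  d3 <- dim(kspaceData(sim3$ks))
  chan3 <- array(complex(real = 0), d3)
  for (v in seq_len(d3[5])) for (c in seq_len(d3[4]))
    chan3[, , , c, v] <- klrcs:::ifftc(kspaceData(sim3$ks)[, , , c, v])
  sos1 <- combineChannels(chan3, method = "sos")
  phase <- exp(1i * 0.7 * seq_len(d3[4]))
  chanPh <- chan3
  for (c in seq_len(d3[4])) chanPh[, , , c, ] <- chanPh[, , , c, ] * phase[c]
  sos2 <- combineChannels(chanPh, method = "sos")
  expect_equal(sos2, sos1, tolerance = 1e-12)
})

test_that("fully sampled KLR reconstruction equals the direct reconstruction", {
  sim <- smallSim(noiseSigma = 0.004)
  msFull <- buildMaskSet(sim$grid, sim$scheme, af = 1, seed = 3)
  direct <- zeroFillRecon(sim$ks)
  rec <- klrReconstruct(sim$ks, msFull, variant = "lrp", nTrain = 300L,
                        outerIters = 3L, preimageMaxIter = 10L, seed = 3,
                        combineMethod = "sos")
  expect_lt(max(abs(rec$volumes - direct)) / max(direct), 1e-12)
  expect_lte(rec$state$iterations, 2L)
})

test_that("KLR reconstruction is deterministic and beats zero-fill at AF 2", {
  sim <- smallSim(noiseSigma = 0.004)
  ms <- buildMaskSet(sim$grid, sim$scheme, af = 2, fsB0 = TRUE, seed = 3)
  us <- retrospectiveUndersample(sim$ks, ms)
  fsM <- scalarMaps(fitTensor(zeroFillRecon(sim$ks), sim$scheme, sim$mask))
  args <- list(kspace = us, maskSet = ms, variant = "lrp", nTrain = 400L,
               outerIters = 4L, preimageMaxIter = 15L, preimageTol = 1e-5,
               thresholdFrac = 0.05, sigmaScale = 0.35, seed = 3,
               combineMethod = "sos")
  rec1 <- do.call(klrReconstruct, args)
  rec2 <- do.call(klrReconstruct, args)
  expect_identical(rec1$volumes, rec2$volumes)
  mKlr <- mapMetrics(rec1$volumes, sim$scheme, sim$mask, fsM)
  mZf <- mapMetrics(zeroFillRecon(us), sim$scheme, sim$mask, fsM)
  expect_lt(mKlr$mdErr, mZf$mdErr)
  expect_lt(mKlr$faErr, mZf$faErr)
  # data-consistency residual shrinks over the outer iterations
  expect_lt(tail(rec1$state$dcResidual, 1), rec1$state$dcResidual[1])
})
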