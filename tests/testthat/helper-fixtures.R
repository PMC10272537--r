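# Shared fixtures, built in code and cached for the session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# Small reference simulation shared across test files: 24 x 24 x 8 phantom,
# 2 b0 + 8 directions, 3 coils, smooth second-order object phase, mild noise.
smallSim <- function(noiseSigma = 0.004, phaseOrder = 2L, seed = 11L) {
  key <- sprintf("sim_%g_%d_%d", noiseSigma, phaseOrder, seed)
  cached(key, {
    shape <- c(24L, 24L, 8L)
    ph <- makePhantom(shape, nTracts = 1L)
    sc <- makeScheme(2L, 8L, 1000)
    co <- makeCoilProfiles(shape, 3L, seed = seed)
    vols <- dwiSignal(ph, sc)
    ks <- simulateKspace(vols, co, sc, phaseOrder = phaseOrder,
                         noiseSigma = noiseSigma, seed = seed)
    list(phantom = ph, scheme = sc, coils = co, vols = vols, ks = ks,
         mask = brainMask(ph), grid = acquisitionGrid(ks))
  })
}

# Median FA/MD percent error and SSIM of a reconstruction against a
# reference map set.
mapMetrics <- function(volumes, scheme, mask, refMaps) {
  m <- scalarMaps(fitTensor(volumes, scheme, mask))
  fa <- medianMetrics(errorMap(faMap(m), faMap(refMaps), mask),
                      ssimMap(faMap(m), faMap(refMaps), mask), mask)
  md <- medianMetrics(errorMap(mdMap(m), mdMap(refMaps), mask),
                      ssimMap(mdMap(m), mdMap(refMaps), mask), mask)
  list(faErr = fa$medianError, mdErr = md$medianError,
       faSsim = fa$medianSSIM, mdSsim = md$medianSSIM)
}
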