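# Comparison metrics and error-source experiments: subpixel rigid shift
# registration, absolute percent-error maps, 3-D SSIM, medians over the
# brain, peak SNR, repetition noise and noise-vs-direction analyses.

#' Estimate and correct a rigid translation between volumes
#'
#' Phase-correlation gives the integer-voxel shift; a continuous refinement
#' then minimises the k-space residual of the phase-ramp-shifted moving
#' volume (equivalently, the image-domain L2 error, by Parseval). The
#' registered volume is produced by the same k-space phase ramp, so
#' subpixel shifts are applied without interpolation loss.
#'
#' @param moving,reference numeric/complex 3-D arrays of equal shape.
#' @return list with \code{shift} (length 3, voxels; the displacement of
#'   \code{moving} relative to \code{reference}) and \code{registered}
#'   (moving shifted by \code{-shift}).
#' @export
registerShift <- function(moving, reference) {
  stopifnot2(identical(dim(moving), dim(reference)),
             "moving and reference must share a shape")
  if (sd(Re(moving)) == 0 || sd(Re(reference)) == 0)
    stop("cannot register flat images (no structure)", call. = FALSE)
  d <- dim(moving)
  Km <- fftc(moving); Kr <- fftc(reference)
  xc <- Re(ifftc(Km * Conj(Kr)))
  peak <- arrayInd(which.max(xc), d)
  intShift <- as.vector(peak) - (d %/% 2L + 1L)
  obj <- function(s) {
    ramp <- shiftRamp(d, -s)      # shift moving back by s
    sum(Mod(Km * ramp - Kr)^2)
  }
  fit <- optim(as.numeric(intShift), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 500))
  s <- fit$par
  registered <- ifftc(Km * shiftRamp(d, -s))
  if (!is.complex(moving)) registered <- Re(registered)
  list(shift = s, registered = registered)
}

#' Absolute percent-error map
#'
#' \code{100 * |test - ref| / max(|ref|, floorFrac * median(|ref| on mask))}
#' with voxels outside the mask set to NA. The floor keeps near-zero
#' reference voxels from exploding the ratio; it is logged into metric
#' reports.
#'
#' @param test,ref arrays of equal shape.
#' @param mask logical array; must select at least one voxel.
#' @param floorFrac denominator floor as a fraction of the masked median
#'   (default 1e-3).
#' @return percent-error array (NA outside the mask).
#' @export
errorMap <- function(test, ref, mask, floorFrac = 1e-3) {
  stopifnot2(identical(dim(test), dim(ref)), "test/ref shape mismatch")
  if (!any(mask)) stop("empty mask", call. = FALSE)
  floorVal <- floorFrac * median(abs(ref[mask]))
  e <- 100 * abs(test - ref) / pmax(abs(ref), floorVal)
  e[!mask] <- NA_real_
  e
}

#' 3-D SSIM map
#'
#' Standard structural-similarity map with a 3-D Gaussian window
#' (sigma = 1.5), K1 = 0.01, K2 = 0.03 and dynamic range equal to
#' max - min of the reference over the mask.
#'
#' @param test,ref numeric 3-D arrays of equal shape.
#' @param mask logical array (used for the dynamic range and downstream
#'   medians; the map itself is computed everywhere and NA'd outside).
#' @param sigma Gaussian window width (voxels).
#' @return SSIM array in [-1, 1] (NA outside the mask).
#' @export
ssimMap <- function(test, ref, mask, sigma = 1.5) {
  stopifnot2(identical(dim(test), dim(ref)), "test/ref shape mismatch")
  if (!any(mask)) stop("empty mask", call. = FALSE)
  L <- diff(range(ref[mask]))
  if (L == 0)
    stop("reference is constant on the mask (zero dynamic range)", call. = FALSE)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu1 <- gaussianFilter3D(test, sigma); mu2 <- gaussianFilter3D(ref, sigma)
  s11 <- gaussianFilter3D(test^2, sigma) - mu1^2
  s22 <- gaussianFilter3D(ref^2, sigma) - mu2^2
  s12 <- gaussianFilter3D(test * ref, sigma) - mu1 * mu2
  ssim <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  ssim <- pmin(pmax(ssim, -1), 1)
  ssim[!mask] <- NA_real_
  ssim
}

#' Median error and SSIM over the mask
#'
#' @param errMap,ssim maps from \code{\link{errorMap}} /
#'   \code{\link{ssimMap}}.
#' @param mask logical array.
#' @return named list(medianError, medianSSIM).
#' @export
medianMetrics <- function(errMap, ssim, mask) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  list(medianError = median(errMap[mask]), medianSSIM = median(ssim[mask]))
}

#' Peak signal-to-noise ratio
#'
#' \code{max(|volume| on mask) / sd(|volume| on background)} — the peak
#' object signal over the background noise level.
#'
#' @param volume numeric/complex 3-D array.
#' @param mask logical object mask.
#' @param background logical background region, disjoint from the mask,
#'   with at least 100 voxels.
#' @return scalar pSNR.
#' @export
psnr <- function(volume, mask, background) {
  stopifnot2(!any(mask & background), "mask and background must be disjoint")
  stopifnot2(sum(background) >= 100, "background must contain >= 100 voxels")
  s <- sd(Mod(volume[background]))
  if (s == 0) stop("zero background noise std; pSNR undefined", call. = FALSE)
  max(Mod(volume[mask])) / s
}

#' Background noise level per diffusion volume
#'
#' Magnitude-image background standard deviation for every volume of a
#' reconstruction, plus its coefficient of variation across the
#' diffusion-weighted volumes — a check that the noise level does not depend
#' on the diffusion direction or its sampling pattern.
#'
#' @param volumes array [nx, ny, nz, nVolumes] (magnitude).
#' @param background logical background region.
#' @param scheme optional \code{\link{DiffusionScheme}} to restrict the
#'   coefficient of variation to weighted volumes.
#' @return list(std = per-volume stds, cv = coefficient of variation).
#' @export
noiseVsDirection <- function(volumes, background, scheme = NULL) {
  nV <- dim(volumes)[4]
  stds <- vapply(seq_len(nV),
                 function(v) sd(Mod(volumes[, , , v][background])), 0)
  dw <- if (is.null(scheme)) seq_len(nV) else which(bValues(scheme) > 0)
  mu <- mean(stds[dw])
  list(std = stds, cv = if (mu == 0) 0 else sd(stds[dw]) / mu)
}

#' Repetition-noise experiment
#'
#' Simulates repeated "acquisitions" of the same phantom with independent
#' noise realisations (and optionally a drift-induced shift), reconstructs
#' each fully sampled dataset directly, and contrasts the FS-vs-FS
#' (repetition) FA/MD error with the CS-reconstruction-vs-own-FS error —
#' the decomposition separating repetition noise from reconstruction error.
#'
#' @param phantom a \code{\link{TensorPhantom}}.
#' @param scheme a \code{\link{DiffusionScheme}}.
#' @param coils a \code{\link{CoilProfiles}}.
#' @param noiseSigma complex-noise std per component.
#' @param seeds two or more integer seeds, one per repetition.
#' @param af acceleration factor for the CS arm (default 2).
#' @param driftPx total drift shift applied to each acquisition (default 0).
#' @param phaseOrder object-phase polynomial order.
#' @param reconArgs extra arguments passed to \code{\link{klrReconstruct}}.
#' @return list with \code{repetition} (FA/MD median error/SSIM between the
#'   two FS repetitions) and \code{cs} (KLR reconstruction vs its own FS
#'   reference), plus the estimated registration shifts.
#' @export
repetitionExperiment <- function(phantom, scheme, coils, noiseSigma, seeds,
                                 af = 2, driftPx = 0, phaseOrder = 2L,
                                 reconArgs = list()) {
  stopifnot2(length(seeds) >= 2, "at least two repetition seeds are required")
  vols <- dwiSignal(phantom, scheme)
  mask <- brainMask(phantom)
  acquire <- function(seed) {
    ks <- simulateKspace(vols, coils, scheme, phaseOrder = phaseOrder,
                         noiseSigma = noiseSigma, seed = seed)
    if (driftPx != 0) ks <- applyDrift(ks, driftPx, axis = 2L)
    ks
  }
  fsMaps <- function(ks, ref = NULL) {
    rec <- zeroFillRecon(ks)
    shifts <- NULL
    if (!is.null(ref)) {
      shifts <- matrix(0, 3, dim(rec)[4])
      for (v in seq_len(dim(rec)[4])) {
        r <- registerShift(rec[, , , v], ref[, , , v])
        rec[, , , v] <- Mod(r$registered)
        shifts[, v] <- r$shift
      }
    } else if (driftPx != 0) {
      refVol <- rec[, , , 1]
      for (v in seq_len(dim(rec)[4])[-1]) {
        r <- registerShift(rec[, , , v], refVol)
        rec[, , , v] <- Mod(r$registered)
      }
    }
    sm <- scalarMaps(fitTensor(rec, scheme, mask))
    list(rec = rec, maps = sm, shifts = shifts)
  }
  ksA <- acquire(seeds[1]); ksB <- acquire(seeds[2])
  fsA <- fsMaps(ksA)
  fsB <- fsMaps(ksB, ref = fsA$rec)
  metricPair <- function(test, ref) {
    list(fa = medianMetrics(errorMap(faMap(test), faMap(ref), mask),
                            ssimMap(faMap(test), faMap(ref), mask), mask),
         md = medianMetrics(errorMap(mdMap(test), mdMap(ref), mask),
                            ssimMap(mdMap(test), mdMap(ref), mask), mask))
  }
  repetition <- metricPair(fsB$maps, fsA$maps)
  grid <- acquisitionGrid(ksA)
  ms <- buildMaskSet(grid, scheme, af, pattern = "monte_carlo",
                     mode = "multi", fsB0 = TRUE, seed = seeds[1])
  us <- retrospectiveUndersample(ksA, ms)
  rec <- do.call(klrReconstruct,
                 c(list(kspace = us, maskSet = ms, seed = seeds[1]), reconArgs))
  csMapsV <- rec$volumes
  if (driftPx != 0) {
    refVol <- fsA$rec[, , , 1]
    for (v in seq_len(dim(csMapsV)[4]))
      csMapsV[, , , v] <- Mod(registerShift(csMapsV[, , , v], refVol)$registered)
  }
  csM <- scalarMaps(fitTensor(csMapsV, scheme, mask))
  cs <- metricPair(csM, fsA$maps)
  list(repetition = repetition, cs = cs, shifts = fsB$shifts)
}
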