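# Undersampling-pattern design over the two phase-encode axes.

# Logical matrix marking the fully sampled central calibration block.
centerBlockIndices <- function(grid) {
  c1 <- abs(centeredIndex(grid@nPE1)) <= grid@centerHalfwidths[1]
  c2 <- abs(centeredIndex(grid@nPE2)) <= grid@centerHalfwidths[2]
  outer(c1, c2, `&`)
}

#' Per-direction acceleration factor under fully sampled b0 volumes
#'
#' The global acceleration factor AF measures the effective scan-time
#' reduction over the whole series. When b0 volumes are kept fully sampled,
#' the diffusion-direction volumes must be undersampled harder to reach the
#' same global AF; this solves
#' \deqn{1/AF = f + (1-f)/AF_{diff}, \quad f = n_{b0}/(n_{b0}+n_{dir})}
#' for \eqn{AF_{diff}}. With 3 b0 + 30 directions, a global AF of 4 requires
#' an AF_diff of 40/7 = 5.714.
#'
#' @param af target global acceleration factor (> 1).
#' @param nB0,nDir counts of b0 and diffusion-direction volumes.
#' @param fsB0 logical; are b0 volumes fully sampled? If \code{FALSE} the
#'   global and per-direction factors coincide and \code{af} is returned.
#' @return the per-diffusion-direction acceleration factor.
#' @examples
#' computeAfDiff(4, 3, 30, fsB0 = TRUE)   # 5.714
#' computeAfDiff(2, 3, 30, fsB0 = FALSE)  # 2
#' @export
computeAfDiff <- function(af, nB0, nDir, fsB0 = TRUE) {
  stopifnot2(af > 1, "af must be > 1")
  if (!fsB0) return(af)
  f <- nB0 / (nB0 + nDir)
  afMax <- (nB0 + nDir) / nB0
  if (af >= afMax)
    stop(sprintf(paste0("global AF = %g is unattainable with %d fully sampled ",
                        "b0s out of %d volumes; the maximum attainable AF is ",
                        "%g (the b0 scan time alone)"),
                 af, nB0, nB0 + nDir, afMax), call. = FALSE)
  (1 - f) / (1 / af - f)
}

#' Variable-density Monte-Carlo sampling probability field
#'
#' Probability density over the PE plane: 1 on the fully sampled central
#' block, and a polynomial radial decay
#' \eqn{(1 - (r - r_0)/(r_{max} - r_0))^p} outside it (floored at 0.01),
#' where r is the elliptical radius normalised so the centre-block edge sits
#' at r = 1. \code{decayPower = 0} gives a uniform density.
#'
#' @param grid a \code{\link{SamplingGrid}}.
#' @param decayPower nonnegative decay exponent p (default 2).
#' @param floor lower bound keeping the density strictly positive.
#' @return numeric [nPE1, nPE2] matrix in (0, 1].
#' @export
monteCarloPdf <- function(grid, decayPower = 2, floor = 0.01) {
  stopifnot2(decayPower >= 0, "decayPower must be >= 0")
  h <- pmax(grid@centerHalfwidths, 1L)
  u <- centeredIndex(grid@nPE1) / h[1]
  v <- centeredIndex(grid@nPE2) / h[2]
  r <- sqrt(outer(u^2, v^2, `+`))          # centre-block edge ~ r = 1
  rmax <- sqrt((max(abs(centeredIndex(grid@nPE1))) / h[1])^2 +
               (max(abs(centeredIndex(grid@nPE2))) / h[2])^2)
  pdf <- pmax((1 - pmax(r - 1, 0) / (rmax - 1))^decayPower, floor)
  pdf[centerBlockIndices(grid)] <- 1
  pdf
}

#' Draw one Monte-Carlo undersampling mask
#'
#' The central block is forced on; the remaining points are drawn without
#' replacement with probability proportional to the density until exactly
#' \code{target} points are sampled, so the per-volume acceleration factor is
#' exact by construction.
#'
#' @param pdf density matrix from \code{\link{monteCarloPdf}}.
#' @param grid the \code{\link{SamplingGrid}} the density was built on.
#' @param target total number of sampled PE points (>= centre-block size).
#' @param seed integer seed; identical seeds give identical masks.
#' @return integer [nPE1, nPE2] 0/1 matrix with \code{sum == target}.
#' @export
sampleMonteCarlo <- function(pdf, grid, target, seed) {
  cb <- centerBlockIndices(grid)
  nCenter <- sum(cb)
  stopifnot2(target >= nCenter,
             sprintf("target (%d) below centre-block size (%d)", target, nCenter))
  stopifnot2(target <= length(pdf), "target exceeds the PE plane size")
  mask <- matrix(0L, nrow(pdf), ncol(pdf))
  mask[cb] <- 1L
  nExtra <- target - nCenter
  if (nExtra > 0) {
    outside <- which(!cb)
    pick <- withSeed(seed,
      sample(outside, nExtra, replace = FALSE, prob = pdf[outside]))
    mask[pick] <- 1L
  }
  mask
}

# Greedy dart-throwing Poisson-disk draw at a given exclusion radius.
# Variable density scales the local radius linearly with the normalised
# elliptical radius; a candidate is accepted when its distance to every
# previously accepted (non-centre) point exceeds the mean of their local
# radii. Returns the 0/1 mask.
poissonDartThrow <- function(grid, rMin, density, scan, seed) {
  n1 <- grid@nPE1; n2 <- grid@nPE2
  u <- centeredIndex(n1); v <- centeredIndex(n2)
  U <- matrix(u, n1, n2); V <- matrix(rep(v, each = n1), n1, n2)
  cb <- centerBlockIndices(grid)
  support <- !cb
  if (scan == "elliptical")
    support <- support & ((2 * U / n1)^2 + (2 * V / n2)^2 <= 1)
  cand <- which(support)
  if (length(cand) == 0)
    stop("elliptical support leaves no candidate points on this grid", call. = FALSE)
  rnorm2 <- sqrt((2 * U / n1)^2 + (2 * V / n2)^2)   # 0 centre -> 1 edge
  localR <- if (density == "variable") rMin * (1 + rnorm2) else
    matrix(rMin, n1, n2)
  ord <- withSeed(seed, sample(length(cand)))
  cand <- cand[ord]
  accX <- numeric(0); accY <- numeric(0); accR <- numeric(0)
  accepted <- integer(0)
  for (idx in cand) {
    x <- U[idx]; y <- V[idx]; r <- localR[idx]
    if (length(accX)) {
      d2 <- (accX - x)^2 + (accY - y)^2
      if (any(d2 < ((accR + r) / 2)^2)) next
    }
    accX <- c(accX, x); accY <- c(accY, y); accR <- c(accR, r)
    accepted <- c(accepted, idx)
  }
  mask <- matrix(0L, n1, n2)
  mask[cb] <- 1L
  mask[accepted] <- 1L
  mask
}

#' Draw one Poisson-disk undersampling mask
#'
#' Dart-throwing Poisson-disk sampling over the PE plane with the central
#' block forced on. The minimum exclusion distance is found by bisection and
#' a seeded random surplus is trimmed (point removal preserves the
#' minimum-distance property), so the achieved per-volume acceleration is
#' exact. Variable density grows the local exclusion radius linearly with
#' the distance from the k-space centre; elliptical scan restricts samples to
#' the inscribed PE-plane ellipse.
#'
#' @param grid a \code{\link{SamplingGrid}}.
#' @param afDiff target per-volume acceleration factor (>= 1).
#' @param density "uniform" or "variable".
#' @param scan "regular" or "elliptical".
#' @param seed integer seed.
#' @param tol relative tolerance on the achieved acceleration (default 0.02).
#' @return integer [nPE1, nPE2] 0/1 matrix.
#' @export
samplePoissonDisk <- function(grid, afDiff, density = c("uniform", "variable"),
                              scan = c("regular", "elliptical"), seed,
                              tol = 0.02) {
  density <- match.arg(density); scan <- match.arg(scan)
  nTot <- grid@nPE1 * grid@nPE2
  if (afDiff <= 1 + 1e-12) {
    if (scan == "elliptical")
      stop("AF ~ 1 is unattainable under an elliptical scan", call. = FALSE)
    return(matrix(1L, grid@nPE1, grid@nPE2))
  }
  target <- nTot / afDiff
  nCenter <- sum(centerBlockIndices(grid))
  if (target < nCenter)
    stop(sprintf(paste0("AF_diff = %g requires fewer samples (%.0f) than the ",
                        "fully sampled centre block (%d); unattainable on ",
                        "this grid"), afDiff, target, nCenter), call. = FALSE)
  target <- round(target)
  # feasibility: densest packing (r -> 0) must reach the target
  maxMask <- poissonDartThrow(grid, 1e-6, density, scan, seed)
  if (sum(maxMask) < target)
    stop(sprintf(paste0("AF_diff = %g unattainable: the %s/%s support admits ",
                        "at most %d samples but %d are required"),
                 afDiff, density, scan, sum(maxMask), target), call. = FALSE)
  # bisection on the exclusion radius, keeping the sparsest mask that still
  # reaches the target count
  lo <- 1e-6; hi <- max(grid@nPE1, grid@nPE2)
  best <- maxMask
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    mask <- poissonDartThrow(grid, mid, density, scan, seed)
    got <- sum(mask)
    if (got >= target) {
      if (got <= sum(best)) best <- mask
      lo <- mid
    } else hi <- mid
    if (got == target) break
  }
  # trim a seeded random surplus outside the centre block: the minimum-
  # distance property survives point removal, and the count becomes exact
  excess <- sum(best) - target
  if (excess > 0) {
    cb <- centerBlockIndices(grid)
    free <- which(best == 1L & !cb)
    if (length(free) < excess)
      stop(sprintf("AF_diff = %g requires trimming into the centre block",
                   afDiff), call. = FALSE)
    drop <- withSeed(seed + 104729L, sample(free, excess))
    best[drop] <- 0L
  }
  best
}

#' Build the per-volume mask set for a diffusion series
#'
#' Generates one sampling pattern per volume according to the pattern family,
#' density, scan support, single/multi-mask mode and b0 handling, with exact
#' acceleration-factor bookkeeping. In multi-mask mode each diffusion volume
#' uses the derived seed \code{seed + volumeIndex}; in single-mask mode all
#' diffusion volumes share one pattern. Under \code{fsB0} the b0 masks are
#' all ones and the diffusion masks absorb the acceleration through
#' \code{\link{computeAfDiff}}.
#'
#' @param grid a \code{\link{SamplingGrid}}.
#' @param scheme a \code{\link{DiffusionScheme}}.
#' @param af target global acceleration factor.
#' @param pattern "monte_carlo" or "poisson_disk".
#' @param density "uniform" or "variable" (Monte-Carlo is always variable
#'   unless \code{decayPower = 0}; for it, "uniform" sets the decay to 0).
#' @param scan "regular" or "elliptical" (Poisson-disk only).
#' @param mode "single" or "multi".
#' @param fsB0 keep b0 volumes fully sampled?
#' @param seed integer seed.
#' @param decayPower Monte-Carlo density decay exponent.
#' @return a \code{\link{MaskSet}}.
#' @export
buildMaskSet <- function(grid, scheme, af,
                         pattern = c("monte_carlo", "poisson_disk"),
                         density = c("variable", "uniform"),
                         scan = c("regular", "elliptical"),
                         mode = c("multi", "single"),
                         fsB0 = TRUE, seed = 1L, decayPower = 2) {
  pattern <- match.arg(pattern); density <- match.arg(density)
  scan <- match.arg(scan); mode <- match.arg(mode)
  b <- bValues(scheme)
  isB0 <- b == 0
  nB0 <- sum(isB0); nDir <- sum(!isB0)
  nVol <- length(b)
  nTot <- grid@nPE1 * grid@nPE2
  afDiff <- if (af <= 1 + 1e-12) 1 else computeAfDiff(af, nB0, nDir, fsB0)
  accel <- new("AccelSpec", af = max(af, 1), afDiff = max(afDiff, 1),
               nB0 = as.integer(nB0), nDir = as.integer(nDir),
               fsB0 = isTRUE(fsB0))
  target <- round(nTot / max(afDiff, 1))
  drawMask <- function(sd) {
    if (max(afDiff, 1) <= 1 + 1e-12) return(matrix(1L, grid@nPE1, grid@nPE2))
    if (pattern == "monte_carlo") {
      p <- if (density == "uniform") 0 else decayPower
      sampleMonteCarlo(monteCarloPdf(grid, p), grid, target, sd)
    } else {
      samplePoissonDisk(grid, afDiff, density, scan, sd)
    }
  }
  masks <- array(0L, c(grid@nPE1, grid@nPE2, nVol))
  full <- matrix(1L, grid@nPE1, grid@nPE2)
  singleMask <- if (mode == "single") drawMask(seed) else NULL
  for (v in seq_len(nVol)) {
    if (fsB0 && isB0[v]) {
      masks[, , v] <- full
    } else if (mode == "single") {
      masks[, , v] <- singleMask
    } else {
      masks[, , v] <- drawMask(seed + v)
    }
  }
  achieved <- (nTot * nVol) / sum(masks)
  ms <- new("MaskSet", masks = masks, pattern = pattern, density = density,
            scan = scan, mode = mode, fsB0 = isTRUE(fsB0), accel = accel,
            achievedAf = achieved, seed = as.integer(seed), grid = grid)
  if (af > 1 && abs(achieved - af) / af > 0.02)
    stop(sprintf("achieved global AF %.4g deviates from target %.4g by more than 2%%",
                 achieved, af), call. = FALSE)
  ms
}
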