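# Kernel low-rank (KLR) CS reconstruction: KPCA self-training on the fully
# sampled k-space centre, voxelwise denoising of the diffusion signal series
# with fixed-point preimage computation, complex recombination (LRP phase
# reattachment or composite real/imaginary stacking), and hard k-space data
# consistency.

#' Low-resolution images and phase maps from the fully sampled k-space centre
#'
#' Zero-fills the k-space of every (coil, volume) outside the central PE
#' block and inverse-transforms, yielding the low-resolution complex images
#' whose magnitudes train the KPCA model and whose phases are the LRP maps.
#'
#' @param kspace a \code{\link{MultiCoilKSpace}}.
#' @param centerHalfwidths centre-block half-widths; defaults to the grid's.
#' @param maskSet optional \code{\link{MaskSet}}; when given, every mask is
#'   checked to fully sample the centre block.
#' @return a \code{\link{LowResPrior}}.
#' @export
extractLowRes <- function(kspace, centerHalfwidths = NULL, maskSet = NULL) {
  g <- acquisitionGrid(kspace)
  h <- if (is.null(centerHalfwidths)) g@centerHalfwidths else
    as.integer(centerHalfwidths)
  cb <- outer(abs(centeredIndex(g@nPE1)) <= h[1],
              abs(centeredIndex(g@nPE2)) <= h[2], `&`)
  if (!is.null(maskSet)) {
    m <- maskArray(maskSet)
    for (v in seq_len(dim(m)[3]))
      if (!all(m[, , v][cb] == 1L))
        stop(sprintf("centre block is not fully sampled in mask %d", v),
             call. = FALSE)
  }
  d <- dim(kspace@data)
  keep <- array(rep(cb, each = d[1]), d[1:3])
  low <- array(complex(real = 0), d)
  for (v in seq_len(d[5])) for (c in seq_len(d[4]))
    low[, , , c, v] <- ifftc(kspace@data[, , , c, v] * keep)
  new("LowResPrior", lowresImages = low, phaseMaps = Arg(low),
      centerHalfwidths = h)
}

# Object-support mask from the low-resolution b0 sum-of-squares image.
lowresObjectMask <- function(prior, thresholdFrac = 0.15, scheme = NULL) {
  low <- prior@lowresImages
  d <- dim(low)
  vols <- if (!is.null(scheme) && any(bValues(scheme) == 0))
    which(bValues(scheme) == 0) else seq_len(d[5])
  sos <- array(0, d[1:3])
  for (v in vols) for (c in seq_len(d[4]))
    sos <- sos + Mod(low[, , , c, v])^2
  sos <- sqrt(sos / length(vols))
  sos > thresholdFrac * quantile(sos, 0.99)
}

# Signal-series matrix (rows = (voxel, coil) pairs, columns = volumes or
# [Re; Im] stacked volumes) from 5-D channel images at given 3-D voxels.
seriesMatrix <- function(channelImages, voxIdx, variant) {
  d <- dim(channelImages)
  nVox <- prod(d[1:3])
  arr <- array(channelImages, c(nVox, d[4], d[5]))[voxIdx, , , drop = FALSE]
  m <- matrix(arr, length(voxIdx) * d[4], d[5])
  switch(variant,
         composite = cbind(Re(m), Im(m)),
         Mod(m))
}

#' Train the Gaussian-kernel PCA model on the low-resolution prior
#'
#' Training samples are per-(voxel, coil) signal series across volumes drawn
#' from voxels inside an intensity-threshold mask of the low-resolution b0
#' sum-of-squares image, subsampled to \code{nTrain} with a seeded sampler.
#' The \code{lrp} and \code{magnitude} variants train on magnitude series
#' (length = number of volumes); \code{composite} trains on the concatenated
#' real and imaginary parts (twice that length). The Gaussian kernel
#' \eqn{k(x,y) = \exp(-\lVert x-y\rVert^2 / 2\sigma_k^2)} uses the median
#' pairwise-distance heuristic for \eqn{\sigma_k} (scalable by
#' \code{sigmaScale}); the kernel matrix is double-centred and its top-rank
#' eigenpairs retained with coefficients normalised so feature-space
#' projections are orthonormal.
#'
#' @param prior a \code{\link{LowResPrior}}.
#' @param variant "lrp", "composite" or "magnitude".
#' @param rank "auto" (smallest rank explaining 99\% of centred-kernel
#'   energy) or a positive integer.
#' @param sigmaScale multiplier on the median-heuristic bandwidth.
#' @param nTrain training-set size cap (default 2000).
#' @param seed integer seed for the voxel subsample.
#' @param thresholdFrac object-mask threshold as a fraction of the 99th
#'   percentile of the low-res b0 SoS image.
#' @param scheme optional \code{\link{DiffusionScheme}} to locate b0 volumes.
#' @param preimage list(maxIter, tol) for later preimage computation.
#' @return a \code{\link{KPCAModel}}.
#' @export
trainKpca <- function(prior, variant = c("lrp", "composite", "magnitude"),
                      rank = "auto", sigmaScale = 1, nTrain = 2000L,
                      seed = 1L, thresholdFrac = 0.15, scheme = NULL,
                      preimage = list(maxIter = 50L, tol = 1e-6)) {
  variant <- match.arg(variant)
  objMask <- lowresObjectMask(prior, thresholdFrac, scheme)
  vox <- which(objMask)
  if (length(vox) == 0)
    stop("empty object mask: the low-resolution prior has no signal", call. = FALSE)
  Xall <- seriesMatrix(prior@lowresImages, vox, variant)
  n <- nrow(Xall)
  pick <- if (n > nTrain) withSeed(seed, sample(n, nTrain)) else seq_len(n)
  X <- Xall[pick, , drop = FALSE]
  if (all(apply(X, 2, function(col) diff(range(col)) == 0)))
    stop(paste0("degenerate training set: all training signals are identical, ",
                "so the kernel matrix carries no structure"), call. = FALSE)
  n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(X), 0)
  medd <- median(sqrt(D2[upper.tri(D2)]))
  if (medd == 0) medd <- sqrt(mean(D2)) + .Machine$double.eps
  sigmaK <- sigmaScale * medd
  K <- exp(-D2 / (2 * sigmaK^2))
  rm1 <- rowMeans(K); tm <- mean(K)
  Kc <- K - outer(rm1, rep(1, n)) - outer(rep(1, n), rm1) + tm
  es <- eigen(Kc, symmetric = TRUE)
  ev <- es$values
  tolEv <- 1e-12 * max(ev, 1)
  pos <- ev > tolEv
  if (identical(rank, "auto")) {
    cs <- cumsum(ev[pos]) / sum(ev[pos])
    r <- max(1L, which(cs >= 0.99)[1])
  } else {
    r <- as.integer(rank)
    stopifnot2(r >= 1L && r <= n, "rank must be in [1, n_train]")
    r <- min(r, sum(pos))
  }
  alphas <- sweep(es$vectors[, seq_len(r), drop = FALSE], 2,
                  sqrt(ev[seq_len(r)]), `/`)
  new("KPCAModel", trainingMatrix = X, variant = variant, sigmaK = sigmaK,
      alphas = alphas, eigvals = pmax(ev, -1e-10 * max(abs(ev))), rank = r,
      preimage = preimage, kRowMeans = rm1, kTotMean = tm)
}

#' Denoise signal series with the KPCA model
#'
#' Projects each signal's feature-space image onto the retained top-rank
#' subspace and computes the preimage with the fixed-point iteration
#' \deqn{z \leftarrow \frac{\sum_i \gamma_i\, k(z, x_i)\, x_i}
#'                         {\sum_i \gamma_i\, k(z, x_i)}}
#' initialised at the input signal, stopping at \code{tol} relative change or
#' \code{maxIter}. Signals whose denominator collapses fall back to the input
#' (with a warning).
#'
#' @param model a \code{\link{KPCAModel}}.
#' @param signals matrix (rows = signals) of length matching the model.
#' @param chunkSize signals processed per block, bounding the kernel-matrix
#'   temporaries (memory, not results, depends on it).
#' @return matrix of the same shape.
#' @export
kpcaDenoise <- function(model, signals, chunkSize = 4096L) {
  if (is.null(dim(signals))) signals <- matrix(signals, 1)
  X <- model@trainingMatrix
  L <- ncol(X); n <- nrow(X)
  stopifnot2(ncol(signals) == L,
             sprintf("signal length %d does not match model length %d",
                     ncol(signals), L))
  s2 <- 2 * model@sigmaK^2
  sqX <- rowSums(X^2)
  kernTo <- function(Z) {
    d2 <- pmax(outer(rowSums(Z^2), sqX, `+`) - 2 * tcrossprod(Z, X), 0)
    exp(-d2 / s2)
  }
  colS <- colSums(model@alphas)
  alphasT <- t(model@alphas)
  m <- nrow(signals)
  out <- signals
  nCollapsed <- 0L
  # signals are processed in chunks to bound the m x n kernel temporaries;
  # within a chunk an active set drops converged signals from the iteration
  for (lo in seq(1L, m, by = chunkSize)) {
    hi <- min(m, lo + chunkSize - 1L)
    S <- signals[lo:hi, , drop = FALSE]
    Ky <- kernTo(S)
    Kc <- Ky - rowMeans(Ky) -
      matrix(model@kRowMeans, nrow(Ky), n, byrow = TRUE) + model@kTotMean
    beta <- Kc %*% model@alphas                    # chunk x r projections
    gamma <- beta %*% alphasT +
      matrix((1 - as.vector(beta %*% colS)) / n, nrow(beta), n)
    Z <- S
    active <- rep(TRUE, nrow(S))
    collapsed <- rep(FALSE, nrow(S))
    for (it in seq_len(model@preimage$maxIter)) {
      if (!any(active)) break
      ia <- which(active)
      Za <- Z[ia, , drop = FALSE]
      W <- gamma[ia, , drop = FALSE] * kernTo(Za)
      den <- rowSums(W)
      bad <- !is.finite(den) | abs(den) < 1e-12
      if (any(bad)) {
        ib <- ia[bad]
        Z[ib, ] <- S[ib, , drop = FALSE]
        collapsed[ib] <- TRUE
        active[ib] <- FALSE
        ia <- ia[!bad]
        if (!length(ia)) break
        W <- W[!bad, , drop = FALSE]; den <- den[!bad]
        Za <- Za[!bad, , drop = FALSE]
      }
      Znew <- (W %*% X) / den
      step <- sqrt(rowSums((Znew - Za)^2)) /
        (sqrt(rowSums(Za^2)) + 1e-12)
      Z[ia, ] <- Znew
      active[ia] <- step >= model@preimage$tol
    }
    nCollapsed <- nCollapsed + sum(collapsed)
    out[lo:hi, ] <- Z
  }
  if (nCollapsed > 0)
    warning(sprintf("kpcaDenoise: denominator collapse for %d signal(s); input returned for those",
                    nCollapsed), call. = FALSE)
  out
}

#' Reattach low-resolution phase to magnitude channel volumes
#'
#' \code{out = magnitude * exp(i * phi)} with the LRP maps of the prior,
#' restoring complex per-channel images usable for data consistency.
#'
#' @param magnitudes numeric array [read, pe1, pe2, coil, volume].
#' @param prior a \code{\link{LowResPrior}} of matching shape.
#' @return complex array of the same shape.
#' @export
reattachPhase <- function(magnitudes, prior) {
  ph <- phaseMaps(prior)
  stopifnot2(identical(dim(magnitudes), dim(ph)),
             "magnitudes and prior phase maps disagree on shape")
  magnitudes * exp(1i * ph)
}

#' Enforce k-space data consistency
#'
#' Replaces estimated k-space values with the acquired values at every
#' sampled location (mask = 1, replicated over coils and readout); unsampled
#' locations keep the estimate.
#'
#' @param estimate,acquired complex arrays [read, pe1, pe2, coil, volume].
#' @param maskSet a \code{\link{MaskSet}} of matching geometry.
#' @return the consistent k-space array.
#' @export
dataConsistency <- function(estimate, acquired, maskSet) {
  d <- dim(estimate)
  if (!identical(d, dim(acquired)))
    stop("estimate and acquired k-space shapes differ", call. = FALSE)
  m <- maskArray(maskSet)
  if (!identical(dim(m)[1:2], d[2:3]) || dim(m)[3] != d[5])
    stop("mask set does not match the k-space geometry", call. = FALSE)
  out <- estimate
  for (v in seq_len(d[5])) {
    sel <- array(rep(m[, , v] == 1L, each = d[1]), d[1:3])
    for (c in seq_len(d[4])) {
      ov <- out[, , , c, v]; av <- acquired[, , , c, v]
      ov[sel] <- av[sel]
      out[, , , c, v] <- ov
    }
  }
  out
}

#' Ratio coil-sensitivity maps
#'
#' \code{map_c = x_c / sqrt(sum_c |x_c|^2)}: the simple sensitivity estimate
#' obtained by dividing each channel image by the sum-of-squares image. Maps
#' are normalised (\code{sum_c |map_c|^2 = 1}) wherever the SoS is positive
#' and 0 (flagged via the \code{"zeroVoxels"} attribute) elsewhere.
#'
#' @param channelImages complex array [nx, ny, nz, nCoils].
#' @return complex array of the same shape with attribute \code{zeroVoxels}.
#' @export
ratioSensitivities <- function(channelImages) {
  d <- dim(channelImages)
  stopifnot2(length(d) == 4L, "channelImages must be [nx, ny, nz, nCoils]")
  sos <- sqrt(apply(Mod(channelImages)^2, 1:3, sum))
  zero <- sos == 0
  sosSafe <- sos; sosSafe[zero] <- 1
  maps <- channelImages / array(rep(sosSafe, d[4]), d)
  maps[array(rep(zero, d[4]), d)] <- 0
  attr(maps, "zeroVoxels") <- zero
  maps
}

#' Combine channel images into one complex series
#'
#' Matched-filter combination \eqn{x = \sum_c \overline{map_c}\, x_{c,v}}
#' with normalised ratio maps, or the sum-of-squares magnitude alternative.
#'
#' @param channelImages complex array [nx, ny, nz, nCoils, nVolumes].
#' @param maps complex array [nx, ny, nz, nCoils] (ignored for SoS).
#' @param method "matched" or "sos".
#' @return array [nx, ny, nz, nVolumes]; complex for matched filter, real
#'   for SoS.
#' @export
combineChannels <- function(channelImages, maps = NULL,
                            method = c("matched", "sos")) {
  method <- match.arg(method)
  d <- dim(channelImages)
  out <- array(if (method == "sos") 0 else complex(real = 0),
               c(d[1:3], d[5]))
  for (v in seq_len(d[5])) {
    xv <- channelImages[, , , , v, drop = FALSE]
    dim(xv) <- d[1:4]
    if (method == "sos") {
      out[, , , v] <- sqrt(apply(Mod(xv)^2, 1:3, sum))
    } else {
      acc <- array(complex(real = 0), d[1:3])
      for (c in seq_len(d[4])) acc <- acc + Conj(maps[, , , c]) * xv[, , , c]
      out[, , , v] <- acc
    }
  }
  out
}

#' Direct zero-filled reconstruction
#'
#' Inverse FFT of the (possibly undersampled) k-space with zeros at
#' unsampled locations, combined across coils by sum of squares. The
#' reference point every CS method must beat, and the identity
#' reconstruction for fully sampled data.
#'
#' @param kspace a \code{\link{MultiCoilKSpace}}.
#' @return magnitude array [read, pe1, pe2, nVolumes].
#' @export
zeroFillRecon <- function(kspace) {
  d <- dim(kspace@data)
  chan <- array(complex(real = 0), d)
  for (v in seq_len(d[5])) for (c in seq_len(d[4]))
    chan[, , , c, v] <- ifftc(kspace@data[, , , c, v])
  combineChannels(chan, method = "sos")
}

#' Kernel low-rank CS reconstruction
#'
#' Full KLR pipeline: extract the low-resolution prior from the fully
#' sampled k-space centre, self-train the KPCA model on it, then iterate
#' from the zero-filled channel images: form per-(voxel, coil) series
#' according to the variant, denoise them with \code{\link{kpcaDenoise}},
#' rebuild complex channel images (LRP phase reattachment, composite Re/Im
#' reassembly, or real-valued for the magnitude-filtered variant), and
#' enforce k-space data consistency — until \code{outerIters} or the
#' relative image change drops below \code{tol}. Channels are combined at
#' the end with ratio sensitivity maps (matched filter) and the magnitude
#' series returned.
#'
#' With all-ones masks (AF = 1) data consistency replaces every sample, so
#' the output equals the direct zero-filled reconstruction after one
#' iteration.
#'
#' @param kspace a \code{\link{MultiCoilKSpace}} (undersampled).
#' @param maskSet the \code{\link{MaskSet}} used for acquisition.
#' @param variant "lrp" (default), "composite" or "magnitude". The
#'   magnitude-filtered variant assumes a real object (Hermitian k-space)
#'   and is retained for comparison; it warns when used.
#' @param rank,sigmaScale,nTrain,thresholdFrac passed to
#'   \code{\link{trainKpca}}.
#' @param outerIters,tol outer-loop controls.
#' @param preimageMaxIter,preimageTol preimage fixed-point controls.
#' @param seed integer seed (training subsample).
#' @param combineMethod "matched" or "sos" final combination.
#' @param verbose print per-iteration progress.
#' @return list with \code{volumes} (magnitude [read, pe1, pe2, nVolumes]),
#'   \code{state} (iteration count, relative-change and data-consistency
#'   residual histories), \code{maps}, \code{model} and \code{objectMask}.
#' @export
klrReconstruct <- function(kspace, maskSet,
                           variant = c("lrp", "composite", "magnitude"),
                           rank = "auto", sigmaScale = 0.35, nTrain = 1000L,
                           outerIters = 6L, tol = 1e-4,
                           preimageMaxIter = 20L, preimageTol = 1e-5,
                           seed = 1L, thresholdFrac = 0.05,
                           combineMethod = "matched", verbose = FALSE) {
  variant <- match.arg(variant)
  if (variant == "magnitude")
    warning(paste0("the magnitude-filtered variant assumes Hermitian (real-",
                   "object) k-space and is not designed for complex acquired ",
                   "data; use \"lrp\" or \"composite\" for those"),
            call. = FALSE)
  d <- dim(kspace@data)
  prior <- extractLowRes(kspace, maskSet = maskSet)
  scheme <- diffusionScheme(kspace)
  model <- trainKpca(prior, variant = variant, rank = rank,
                     sigmaScale = sigmaScale, nTrain = nTrain, seed = seed,
                     thresholdFrac = thresholdFrac, scheme = scheme,
                     preimage = list(maxIter = as.integer(preimageMaxIter),
                                     tol = preimageTol))
  objMask <- lowresObjectMask(prior, thresholdFrac, scheme)
  vox <- which(objMask)
  nVox <- prod(d[1:3]); nC <- d[4]; nV <- d[5]
  d3 <- d[1:3]
  # flat layout: one column per (coil, volume), coil fastest — cuts copying
  acqM <- matrix(kspace@data, nVox, nC * nV)
  chanM <- acqM
  for (j in seq_len(ncol(chanM)))
    chanM[, j] <- as.vector(ifftc(array(acqM[, j], d3)))
  m <- maskArray(maskSet)
  selV <- lapply(seq_len(nV), function(v)
    as.vector(array(rep(m[, , v] == 1L, each = d[1]), d3)))
  volOf <- rep(seq_len(nV), each = nC)
  phSub <- if (variant == "lrp") {
    arr <- array(phaseMaps(prior), c(nVox, nC, nV))[vox, , , drop = FALSE]
    matrix(arr, length(vox) * nC, nV)
  } else NULL
  relHist <- numeric(0); dcHist <- numeric(0)
  for (it in seq_len(outerIters)) {
    prev <- chanM
    A <- chanM[vox, , drop = FALSE]                # (voxel, coil-fastest cols)
    Am <- matrix(A, length(vox) * nC, nV)          # rows = (voxel, coil) pairs
    sig <- if (variant == "composite") cbind(Re(Am), Im(Am)) else Mod(Am)
    den <- kpcaDenoise(model, sig)
    newSeries <- switch(variant,
      lrp = pmax(den, 0) * exp(1i * phSub),
      magnitude = complex(real = pmax(den, 0)),
      composite = {
        half <- ncol(den) / 2
        matrix(complex(real = den[, seq_len(half)],
                       imaginary = den[, half + seq_len(half)]),
               nrow(den), half)
      })
    upd <- matrix(newSeries, length(vox), nC * nV)
    chanM[vox, ] <- upd
    res <- 0
    for (j in seq_len(ncol(chanM))) {
      kj <- as.vector(fftc(array(chanM[, j], d3)))
      sel <- selV[[volOf[j]]]
      res <- res + sum(Mod(kj[sel] - acqM[sel, j])^2)
      kj[sel] <- acqM[sel, j]                      # hard data consistency
      chanM[, j] <- as.vector(ifftc(array(kj, d3)))
    }
    dcHist <- c(dcHist, sqrt(res))
    rel <- relDiff(chanM, prev)
    relHist <- c(relHist, rel)
    if (verbose)
      message(sprintf("KLR %s iter %d: rel change %.3g, DC residual %.3g",
                      variant, it, rel, dcHist[it]))
    if (rel < tol) break
  }
  chan <- array(chanM, d)
  b0s <- which(bValues(scheme) == 0)
  if (!length(b0s)) b0s <- 1L
  agg <- array(complex(real = 0), c(d3, nC))
  for (c in seq_len(nC)) {
    cols <- c + (b0s - 1L) * nC
    agg[, , , c] <- array(rowMeans(chanM[, cols, drop = FALSE]), d3)
  }
  maps <- ratioSensitivities(agg)
  combined <- combineChannels(chan, maps, method = combineMethod)
  list(volumes = Mod(combined),
       state = list(iterations = length(relHist), relChange = relHist,
                    dcResidual = dcHist),
       maps = maps, model = model, objectMask = objMask)
}
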