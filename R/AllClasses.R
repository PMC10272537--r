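# Central S4 containers. Arrays follow R column-major layout:
#   images/k-space volumes: [read, pe1, pe2] (+ coil, + volume)
#   masks:                  [pe1, pe2, volume]
# DC / image centre sits at index n %/% 2 + 1 along each axis (see fftc()).

#' SamplingGrid: acquisition matrix and fully sampled k-space centre
#'
#' Describes the 3-D acquisition grid: a fully sampled readout axis and the
#' two phase-encode (PE) axes over which undersampling operates, plus the
#' half-widths of the rectangular fully sampled central PE block used for
#' calibration and KLR self-training.
#'
#' @slot nRead integer, readout points.
#' @slot nPE1,nPE2 integer, phase-encode matrix size.
#' @slot centerHalfwidths integer(2), half-widths of the fully sampled central
#'   PE block; the block has \code{(2*h1+1)*(2*h2+1)} points.
#' @export
setClass("SamplingGrid",
  representation(nRead = "integer", nPE1 = "integer", nPE2 = "integer",
                 centerHalfwidths = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(c(object@nRead, object@nPE1, object@nPE2) < 4L))
      msg <- c(msg, "all grid dimensions must be >= 4")
    h <- object@centerHalfwidths
    if (length(h) != 2L || any(h < 0L))
      msg <- c(msg, "centerHalfwidths must be two nonnegative integers")
    else if (2L * h[1] + 1L >= object@nPE1 || 2L * h[2] + 1L >= object@nPE2)
      msg <- c(msg, "centre block must lie strictly inside the PE plane")
    if (length(msg)) msg else TRUE
  })

#' Construct a SamplingGrid
#'
#' @param nRead,nPE1,nPE2 grid dimensions (readout, PE1, PE2), each >= 4.
#' @param centerHalfwidths half-widths of the fully sampled central PE block;
#'   default 1/8 of each PE dimension. The centre size drives calibration and
#'   KLR training quality and caps the attainable acceleration (the centre is
#'   always sampled), so it is exposed as configuration; the default was
#'   chosen by simulation on the reference phantom (see the vignette).
#' @return a \code{SamplingGrid}.
#' @export
samplingGrid <- function(nRead, nPE1, nPE2,
                         centerHalfwidths = c(max(1L, nPE1 %/% 8L),
                                              max(1L, nPE2 %/% 8L))) {
  new("SamplingGrid", nRead = as.integer(nRead), nPE1 = as.integer(nPE1),
      nPE2 = as.integer(nPE2), centerHalfwidths = as.integer(centerHalfwidths))
}

#' AccelSpec: acceleration-factor bookkeeping
#'
#' The global acceleration factor \code{af} is the effective reduction in
#' scan time over the whole series (b0 volumes + diffusion directions). When
#' b0 volumes are kept fully sampled (\code{fsB0 = TRUE}) the per-direction
#' factor \code{afDiff} must exceed \code{af} to compensate, following
#' \deqn{1/AF = f + (1-f)/AF_{diff}, \quad f = n_{b0}/(n_{b0}+n_{dir}).}
#'
#' @slot af global acceleration factor (> 1 for genuine undersampling).
#' @slot afDiff acceleration factor applied to each diffusion direction.
#' @slot nB0,nDir integer volume counts.
#' @slot fsB0 logical; are b0 volumes fully sampled?
#' @export
setClass("AccelSpec",
  representation(af = "numeric", afDiff = "numeric", nB0 = "integer",
                 nDir = "integer", fsB0 = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@nB0 < 1L) msg <- c(msg, "nB0 must be >= 1")
    if (object@nDir < 6L) msg <- c(msg, "nDir must be >= 6")
    if (object@af < 1) msg <- c(msg, "af must be >= 1")
    f <- object@nB0 / (object@nB0 + object@nDir)
    if (object@fsB0) {
      lhs <- 1 / object@af
      rhs <- f + (1 - f) / object@afDiff
      if (abs(lhs - rhs) > 1e-8)
        msg <- c(msg, "afDiff inconsistent with af under fully sampled b0s")
    } else if (abs(object@afDiff - object@af) > 1e-8) {
      msg <- c(msg, "afDiff must equal af when b0s are undersampled too")
    }
    if (length(msg)) msg else TRUE
  })

#' MaskSet: per-volume k-space undersampling patterns
#'
#' Binary sampling patterns over the PE plane, one per volume, with their
#' acceleration bookkeeping. The central calibration block is always fully
#' sampled; under \code{fsB0} every b0 mask is all ones.
#'
#' @slot masks integer array [pe1, pe2, volume] of 0/1.
#' @slot pattern "monte_carlo" or "poisson_disk".
#' @slot density "uniform" or "variable".
#' @slot scan "regular" or "elliptical".
#' @slot mode "single" (one shared diffusion mask) or "multi" (per volume).
#' @slot fsB0 logical.
#' @slot accel an \code{\link{AccelSpec}}.
#' @slot achievedAf realised global acceleration factor.
#' @slot seed integer seed that generated the set.
#' @slot grid the \code{\link{SamplingGrid}}.
#' @export
setClass("MaskSet",
  representation(masks = "array", pattern = "character", density = "character",
                 scan = "character", mode = "character", fsB0 = "logical",
                 accel = "AccelSpec", achievedAf = "numeric", seed = "integer",
                 grid = "SamplingGrid"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@masks)
    g <- object@grid
    if (length(d) != 3L || d[1] != g@nPE1 || d[2] != g@nPE2)
      msg <- c(msg, "masks must be [nPE1, nPE2, nVolumes]")
    if (!all(object@masks %in% c(0L, 1L)))
      msg <- c(msg, "masks must be binary")
    cb <- centerBlockIndices(g)
    for (v in seq_len(dim(object@masks)[3]))
      if (!all(object@masks[, , v][cb] == 1L)) {
        msg <- c(msg, "central calibration block must be fully sampled in every mask")
        break
      }
    if (length(msg)) msg else TRUE
  })

#' DiffusionScheme: b-values and gradient directions
#'
#' @slot bvals numeric b-values (s/mm^2), one per volume.
#' @slot bvecs 3 x nVolumes matrix of gradient directions; unit columns for
#'   diffusion-weighted volumes, zero columns allowed for b0s.
#' @export
setClass("DiffusionScheme",
  representation(bvals = "numeric", bvecs = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@bvecs) != 3L)
      msg <- c(msg, "bvecs must be a 3 x nVolumes matrix")
    if (ncol(object@bvecs) != length(object@bvals))
      msg <- c(msg, "bvals and bvecs disagree on volume count")
    if (any(object@bvals < 0)) msg <- c(msg, "b-values must be nonnegative")
    dw <- object@bvals > 0
    if (any(dw)) {
      nrm <- sqrt(colSums(object@bvecs[, dw, drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "gradient directions must be unit vectors where b > 0")
    }
    if (length(msg)) msg else TRUE
  })

#' TensorPhantom: voxelwise diffusion-tensor ground truth
#'
#' @slot shape integer(3) grid size.
#' @slot D numeric array [nx, ny, nz, 6], tensor components ordered
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in mm^2/s.
#' @slot S0 nonnegative proton-density volume; 0 outside the mask.
#' @slot mask logical brain mask.
#' @slot labels integer region labels (0 background).
#' @export
setClass("TensorPhantom",
  representation(shape = "integer", D = "array", S0 = "array",
                 mask = "array", labels = "array"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@S0), as.integer(object@shape)))
      msg <- c(msg, "S0 shape mismatch")
    if (!identical(dim(object@D)[1:3], as.integer(object@shape)) ||
        dim(object@D)[4] != 6L)
      msg <- c(msg, "D must be [shape, 6]")
    if (any(object@S0[!object@mask] != 0))
      msg <- c(msg, "S0 must be 0 outside the mask")
    if (length(msg)) msg else TRUE
  })

#' CoilProfiles: smooth complex receive sensitivities
#'
#' @slot profiles complex array [nx, ny, nz, nCoils].
#' @export
setClass("CoilProfiles", representation(profiles = "array"))

#' MultiCoilKSpace: the central acquisition object
#'
#' Complex k-space samples of a diffusion series received on several coils.
#'
#' @slot data complex array [read, pe1, pe2, coil, volume] under the shared
#'   centred orthonormal FFT convention.
#' @slot grid a \code{\link{SamplingGrid}}.
#' @slot scheme a \code{\link{DiffusionScheme}}.
#' @slot noiseSigma per-component complex Gaussian noise std used in
#'   simulation (NA for data of unknown provenance).
#' @slot seed integer simulation seed.
#' @export
setClass("MultiCoilKSpace",
  representation(data = "array", grid = "SamplingGrid",
                 scheme = "DiffusionScheme", noiseSigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    d <- dim(object@data)
    g <- object@grid
    msg <- character()
    if (length(d) != 5L)
      msg <- c(msg, "data must be [read, pe1, pe2, coil, volume]")
    else {
      if (!identical(d[1:3], c(g@nRead, g@nPE1, g@nPE2)))
        msg <- c(msg, "data grid dimensions disagree with the SamplingGrid")
      if (d[5] != length(object@scheme@bvals))
        msg <- c(msg, "volume count disagrees with the diffusion scheme")
    }
    if (length(msg)) msg else TRUE
  })

#' LowResPrior: low-resolution images and phase maps from the k-space centre
#'
#' Per-(coil, volume) complex images reconstructed from the fully sampled
#' central PE block only (zero-filled elsewhere), plus their phase maps. The
#' phases are the low-resolution-phase (LRP) maps reattached to denoised
#' magnitudes during KLR reconstruction; the images are the KLR training data.
#'
#' @slot lowresImages complex array [read, pe1, pe2, coil, volume].
#' @slot phaseMaps numeric array of the same shape, values in (-pi, pi].
#' @slot centerHalfwidths integer(2) PE-centre half-widths used.
#' @export
setClass("LowResPrior",
  representation(lowresImages = "array", phaseMaps = "array",
                 centerHalfwidths = "integer"))

#' KPCAModel: Gaussian-kernel PCA model for voxel signal series
#'
#' @slot trainingMatrix n_train x L matrix of training signals (rows).
#' @slot variant "lrp", "composite" or "magnitude"; decides how complex voxel
#'   series map to training rows (magnitude for lrp/magnitude, stacked
#'   real/imaginary parts for composite).
#' @slot sigmaK Gaussian kernel bandwidth.
#' @slot alphas n_train x r eigencoefficients of the double-centred kernel
#'   matrix, scaled so feature-space projections are orthonormal.
#' @slot eigvals centred-kernel eigenvalues, nonincreasing.
#' @slot rank retained subspace rank r.
#' @slot preimage list(maxIter, tol) for the fixed-point preimage iteration.
#' @slot kRowMeans,kTotMean centring statistics of the training kernel matrix.
#' @export
setClass("KPCAModel",
  representation(trainingMatrix = "matrix", variant = "character",
                 sigmaK = "numeric", alphas = "matrix", eigvals = "numeric",
                 rank = "integer", preimage = "list", kRowMeans = "numeric",
                 kTotMean = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@rank < 1L || object@rank > nrow(object@trainingMatrix))
      msg <- c(msg, "rank must be in [1, n_train]")
    if (object@sigmaK <= 0) msg <- c(msg, "sigmaK must be positive")
    if (is.unsorted(rev(object@eigvals), strictly = FALSE))
      msg <- c(msg, "eigenvalues must be nonincreasing")
    if (any(object@eigvals < -1e-10 * max(abs(object@eigvals), 1)))
      msg <- c(msg, "centred kernel matrix must be PSD within tolerance")
    if (length(msg)) msg else TRUE
  })

#' TensorFit: voxelwise log-linear diffusion tensor estimates
#'
#' @slot D numeric array [nx, ny, nz, 6] (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @slot lnS0 numeric array, fitted log baseline signal.
#' @slot fitMask logical array of voxels actually fitted.
#' @slot residRms numeric array of per-voxel residual RMS in log space.
#' @export
setClass("TensorFit",
  representation(D = "array", lnS0 = "array", fitMask = "array",
                 residRms = "array"))

#' ScalarMaps: FA and MD maps derived from a tensor fit
#'
#' @slot fa fractional anisotropy, clamped into [0, 1].
#' @slot md mean diffusivity (mm^2/s).
#' @slot clamped logical array flagging voxels whose negative eigenvalues
#'   were clamped to zero before computing FA.
#' @export
setClass("ScalarMaps",
  representation(fa = "array", md = "array", clamped = "array"),
  validity = function(object) {
    if (any(object@fa < 0 | object@fa > 1, na.rm = TRUE))
      "FA must lie in [0, 1]" else TRUE
  })
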