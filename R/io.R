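# Container and image I/O. The native on-disk container is a structured,
# versioned RDS file holding the complex k-space array, masks, scheme and
# provenance attributes; images travel as NIfTI-1 via RNifti; diffusion
# schemes as FSL-style bval/bvec text (see readScheme/writeScheme).

CONTAINER_VERSION <- 1L

#' Write and read the k-space container
#'
#' Stores a \code{\link{MultiCoilKSpace}}, optionally with its
#' \code{\link{MaskSet}} and ground-truth \code{\link{CoilProfiles}}, to a
#' single container file. Complex data round-trip bit-exactly. The layout
#' (arrays: kspace [read, pe1, pe2, coil, volume]; masks [pe1, pe2, volume];
#' bvals/bvecs; attributes: fft convention, seed, noise sigma, centre
#' half-widths) mirrors the package's in-memory objects; the FFT convention
#' recorded is "centered-orthonormal, DC at n %/% 2 + 1".
#'
#' @param kspace a \code{\link{MultiCoilKSpace}}.
#' @param path output file path.
#' @param maskSet optional \code{\link{MaskSet}}.
#' @param coils optional \code{\link{CoilProfiles}} ground truth.
#' @return \code{readKspaceContainer}: list with elements \code{kspace},
#'   \code{maskSet} (or NULL) and \code{coils} (or NULL).
#' @export
writeKspaceContainer <- function(kspace, path, maskSet = NULL, coils = NULL) {
  g <- acquisitionGrid(kspace)
  obj <- list(
    version = CONTAINER_VERSION,
    fft_convention = "centered-orthonormal, DC at n %/% 2 + 1",
    kspace = kspaceData(kspace),
    bvals = bValues(diffusionScheme(kspace)),
    bvecs = bVectors(diffusionScheme(kspace)),
    noise_sigma = kspace@noiseSigma,
    seed = kspace@seed,
    grid = c(nRead = g@nRead, nPE1 = g@nPE1, nPE2 = g@nPE2),
    center_halfwidths = g@centerHalfwidths,
    masks = if (!is.null(maskSet)) maskArray(maskSet) else NULL,
    mask_meta = if (!is.null(maskSet)) list(
      pattern = maskSet@pattern, density = maskSet@density,
      scan = maskSet@scan, mode = maskSet@mode, fs_b0 = maskSet@fsB0,
      af = maskSet@accel@af, af_diff = maskSet@accel@afDiff,
      achieved_af = achievedAF(maskSet), seed = maskSet@seed) else NULL,
    coil_profiles = if (!is.null(coils)) coilArray(coils) else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeKspaceContainer
#' @export
readKspaceContainer <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such container: %s", path),
                               call. = FALSE)
  obj <- readRDS(path)
  for (f in c("version", "kspace", "bvals", "bvecs", "grid",
              "center_halfwidths"))
    if (is.null(obj[[f]]))
      stop(sprintf("malformed container %s: missing field '%s'", path, f),
           call. = FALSE)
  scheme <- new("DiffusionScheme", bvals = obj$bvals, bvecs = obj$bvecs)
  grid <- samplingGrid(obj$grid["nRead"], obj$grid["nPE1"], obj$grid["nPE2"],
                       centerHalfwidths = obj$center_halfwidths)
  ks <- new("MultiCoilKSpace", data = obj$kspace, grid = grid,
            scheme = scheme,
            noiseSigma = if (is.null(obj$noise_sigma)) NA_real_ else obj$noise_sigma,
            seed = if (is.null(obj$seed)) NA_integer_ else as.integer(obj$seed))
  maskSet <- NULL
  if (!is.null(obj$masks)) {
    mm <- obj$mask_meta
    nB0 <- sum(obj$bvals == 0); nDir <- sum(obj$bvals > 0)
    accel <- new("AccelSpec", af = mm$af, afDiff = mm$af_diff,
                 nB0 = as.integer(nB0), nDir = as.integer(nDir),
                 fsB0 = mm$fs_b0)
    maskSet <- new("MaskSet", masks = obj$masks, pattern = mm$pattern,
                   density = mm$density, scan = mm$scan, mode = mm$mode,
                   fsB0 = mm$fs_b0, accel = accel,
                   achievedAf = mm$achieved_af, seed = as.integer(mm$seed),
                   grid = grid)
  }
  coils <- if (!is.null(obj$coil_profiles))
    new("CoilProfiles", profiles = obj$coil_profiles) else NULL
  list(kspace = ks, maskSet = maskSet, coils = coils)
}

#' Write and read volume series as NIfTI-1
#'
#' Thin wrappers over RNifti preserving a supplied affine through the
#' pipeline.
#'
#' @param volumes 3-D or 4-D numeric array.
#' @param path .nii or .nii.gz path.
#' @param pixdim voxel dimensions (mm), length 3.
#' @return \code{readVolumes}: the array with attribute \code{pixdim}.
#' @export
writeVolumes <- function(volumes, path, pixdim = c(1, 1, 1)) {
  attr(volumes, "pixdim") <- pixdim
  img <- RNifti::asNifti(volumes, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname writeVolumes
#' @export
readVolumes <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}
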