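# Accessor generics. Slots are never reached into from user code.

#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @export
setGeneric("achievedAF", function(x) standardGeneric("achievedAF"))
#' @export
setGeneric("kspaceData", function(x) standardGeneric("kspaceData"))
#' @export
setGeneric("acquisitionGrid", function(x) standardGeneric("acquisitionGrid"))
#' @export
setGeneric("diffusionScheme", function(x) standardGeneric("diffusionScheme"))
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))
#' @export
setGeneric("faMap", function(x) standardGeneric("faMap"))
#' @export
setGeneric("mdMap", function(x) standardGeneric("mdMap"))
#' @export
setGeneric("phaseMaps", function(x) standardGeneric("phaseMaps"))
#' @export
setGeneric("lowresImages", function(x) standardGeneric("lowresImages"))
#' @export
setGeneric("coilArray", function(x) standardGeneric("coilArray"))
#' @export
setGeneric("tensorArray", function(x) standardGeneric("tensorArray"))
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' Accessors for klrcs containers
#'
#' \code{nVolumes} returns the number of volumes in a scheme, mask set or
#' k-space object; \code{maskArray} the [pe1, pe2, volume] 0/1 array;
#' \code{achievedAF} the realised global acceleration factor;
#' \code{kspaceData} the complex [read, pe1, pe2, coil, volume] array;
#' \code{acquisitionGrid} and \code{diffusionScheme} the embedded descriptors;
#' \code{bValues}/\code{bVectors} the diffusion scheme columns;
#' \code{faMap}/\code{mdMap} the scalar maps; \code{phaseMaps} and
#' \code{lowresImages} the LRP prior contents; \code{coilArray} the complex
#' coil-profile array; \code{tensorArray} the [nx,ny,nz,6] tensor components;
#' \code{brainMask} the logical mask of a phantom.
#'
#' @param x a klrcs container object.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("nVolumes", "DiffusionScheme", function(x) length(x@bvals))
#' @rdname accessors
setMethod("nVolumes", "MaskSet", function(x) dim(x@masks)[3])
#' @rdname accessors
setMethod("nVolumes", "MultiCoilKSpace", function(x) dim(x@data)[5])
#' @rdname accessors
setMethod("maskArray", "MaskSet", function(x) x@masks)
#' @rdname accessors
setMethod("achievedAF", "MaskSet", function(x) x@achievedAf)
#' @rdname accessors
setMethod("kspaceData", "MultiCoilKSpace", function(x) x@data)
#' @rdname accessors
setMethod("acquisitionGrid", "MultiCoilKSpace", function(x) x@grid)
#' @rdname accessors
setMethod("acquisitionGrid", "MaskSet", function(x) x@grid)
#' @rdname accessors
setMethod("diffusionScheme", "MultiCoilKSpace", function(x) x@scheme)
#' @rdname accessors
setMethod("bValues", "DiffusionScheme", function(x) x@bvals)
#' @rdname accessors
setMethod("bVectors", "DiffusionScheme", function(x) x@bvecs)
#' @rdname accessors
setMethod("faMap", "ScalarMaps", function(x) x@fa)
#' @rdname accessors
setMethod("mdMap", "ScalarMaps", function(x) x@md)
#' @rdname accessors
setMethod("phaseMaps", "LowResPrior", function(x) x@phaseMaps)
#' @rdname accessors
setMethod("lowresImages", "LowResPrior", function(x) x@lowresImages)
#' @rdname accessors
setMethod("coilArray", "CoilProfiles", function(x) x@profiles)
#' @rdname accessors
setMethod("tensorArray", "TensorPhantom", function(x) x@D)
#' @rdname accessors
setMethod("tensorArray", "TensorFit", function(x) x@D)
#' @rdname accessors
setMethod("brainMask", "TensorPhantom", function(x) x@mask)

setMethod("show", "SamplingGrid", function(object) {
  cat(sprintf("SamplingGrid %d x %d x %d (read x PE1 x PE2), FS centre half-widths (%d, %d)\n",
              object@nRead, object@nPE1, object@nPE2,
              object@centerHalfwidths[1], object@centerHalfwidths[2]))
})

setMethod("show", "AccelSpec", function(object) {
  cat(sprintf("AccelSpec AF = %.3g, AF_diff = %.4g, %d b0 + %d directions, b0s %s\n",
              object@af, object@afDiff, object@nB0, object@nDir,
              if (object@fsB0) "fully sampled" else "undersampled"))
})

setMethod("show", "MaskSet", function(object) {
  d <- dim(object@masks)
  cat(sprintf("MaskSet: %d masks on a %d x %d PE plane\n", d[3], d[1], d[2]))
  cat(sprintf("  pattern %s (%s density, %s scan), %s-mask, seed %d\n",
              object@pattern, object@density, object@scan, object@mode,
              object@seed))
  cat(sprintf("  target AF %.3g (AF_diff %.4g), achieved AF %.4g\n",
              object@accel@af, object@accel@afDiff, object@achievedAf))
})

setMethod("show", "DiffusionScheme", function(object) {
  nb0 <- sum(object@bvals == 0)
  cat(sprintf("DiffusionScheme: %d volumes (%d b0 + %d weighted), b up to %g s/mm^2\n",
              length(object@bvals), nb0, length(object@bvals) - nb0,
              max(object@bvals)))
})

setMethod("show", "TensorPhantom", function(object) {
  cat(sprintf("TensorPhantom %s, %d mask voxels, regions: %s\n",
              paste(object@shape, collapse = " x "), sum(object@mask),
              paste(sort(unique(as.vector(object@labels[object@labels > 0]))),
                    collapse = ", ")))
})

setMethod("show", "MultiCoilKSpace", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultiCoilKSpace: %d coils x %d volumes on %d x %d x %d grid (noise sigma %.4g)\n",
              d[4], d[5], d[1], d[2], d[3], object@noiseSigma))
})

setMethod("show", "KPCAModel", function(object) {
  cat(sprintf("KPCAModel (%s): %d training signals of length %d, sigma_k %.4g, rank %d\n",
              object@variant, nrow(object@trainingMatrix),
              ncol(object@trainingMatrix), object@sigmaK, object@rank))
})

setMethod("show", "ScalarMaps", function(object) {
  cat(sprintf("ScalarMaps %s: FA in [%.3f, %.3f], MD in [%.3g, %.3g] mm^2/s\n",
              paste(dim(object@fa), collapse = " x "),
              min(object@fa), max(object@fa), min(object@md), max(object@md)))
})
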