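# Diffusion schemes: b-values plus unit gradient directions.

#' Construct a diffusion scheme
#'
#' Places \code{nDir} diffusion directions quasi-uniformly over the half
#' sphere with a Fibonacci spiral (a deterministic stand-in for
#' electrostatic-repulsion direction sets), preceded by \code{nB0} b = 0
#' volumes.
#'
#' @param nB0 number of b0 volumes (default 3).
#' @param nDir number of diffusion directions (>= 6; default 30).
#' @param b diffusion weighting of the weighted volumes (s/mm^2).
#' @return a \code{\link{DiffusionScheme}}.
#' @export
makeScheme <- function(nB0 = 3L, nDir = 30L, b = 1000) {
  stopifnot2(nDir >= 6, "at least 6 diffusion directions are required")
  i <- seq_len(nDir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / nDir                     # upper half sphere avoids antipodal pairs
  r <- sqrt(pmax(0, 1 - z^2))
  g <- rbind(r * cos(phi), r * sin(phi), z)
  g <- sweep(g, 2, sqrt(colSums(g^2)), `/`)
  bv <- c(rep(0, nB0), rep(b, nDir))
  vecs <- cbind(matrix(0, 3, nB0), g)
  dimnames(vecs) <- NULL
  new("DiffusionScheme", bvals = bv, bvecs = vecs)
}

#' Read and write FSL-style bval/bvec text files
#'
#' \code{readScheme} accepts both the FSL 3 x N row layout and an N x 3
#' column layout for the bvec file (auto-detected) and renormalises weighted
#' directions to unit length. \code{writeScheme} emits the FSL 3 x N dialect.
#'
#' @param bvalFile,bvecFile paths to whitespace-separated text files.
#' @return \code{readScheme}: a \code{\link{DiffusionScheme}}.
#' @export
readScheme <- function(bvalFile, bvecFile) {
  bvals <- scan(bvalFile, quiet = TRUE)
  m <- as.matrix(read.table(bvecFile))
  if (nrow(m) != 3L && ncol(m) == 3L) m <- t(m)
  if (nrow(m) != 3L)
    stop("bvec file must hold a 3 x N (or N x 3) direction table", call. = FALSE)
  if (ncol(m) != length(bvals))
    stop(sprintf("bvec has %d volumes but bval has %d", ncol(m), length(bvals)),
         call. = FALSE)
  dw <- bvals > 0
  nrm <- sqrt(colSums(m^2))
  if (any(dw & nrm == 0))
    stop("zero gradient vector on a diffusion-weighted volume", call. = FALSE)
  m[, dw] <- sweep(m[, dw, drop = FALSE], 2, nrm[dw], `/`)
  m[, !dw] <- 0
  dimnames(m) <- NULL
  new("DiffusionScheme", bvals = bvals, bvecs = m)
}

#' @rdname readScheme
#' @param scheme a \code{\link{DiffusionScheme}} to write.
#' @export
writeScheme <- function(scheme, bvalFile, bvecFile) {
  writeLines(paste(format(bValues(scheme), trim = TRUE), collapse = " "),
             bvalFile)
  write.table(format(bVectors(scheme), trim = TRUE, digits = 15), bvecFile,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(NULL)
}
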