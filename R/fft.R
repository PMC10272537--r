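# Centered orthonormal FFT convention shared by every module.
#
# fftc:  image -> k-space, DC at (n %/% 2 + 1) along each axis, unitary
#        scaling 1/sqrt(N) so Parseval holds with factor 1 exactly.
# ifftc: the adjoint/inverse.

circShift <- function(x, shifts) {
  d <- base::dim(x)
  if (is.null(d)) {
    n <- length(x)
    s <- shifts[1] %% n
    if (s == 0) return(x)
    return(x[c((n - s + 1):n, 1:(n - s))])
  }
  idx <- lapply(seq_along(d), function(k) {
    n <- d[k]
    s <- shifts[k] %% n
    if (s == 0) seq_len(n) else c((n - s + 1):n, 1:(n - s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

fftShift <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  circShift(x, d %/% 2L)
}

ifftShift <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  circShift(x, -(d %/% 2L))
}

#' Centered orthonormal n-dimensional FFT
#'
#' Forward transform from image space to k-space with the DC component at
#' index \code{n \%/\% 2 + 1} along each axis and unitary (\code{1/sqrt(N)})
#' scaling, so that energy is preserved exactly (Parseval factor 1).
#'
#' @param x real or complex vector/array.
#' @return complex array of the same shape.
#' @export
fftc <- function(x) {
  fftShift(fft(ifftShift(x))) / sqrt(length(x))
}

#' @rdname fftc
#' @export
ifftc <- function(x) {
  fftShift(fft(ifftShift(x), inverse = TRUE)) / sqrt(length(x))
}

# Apply fftc/ifftc over the first three dims of a [nx,ny,nz,...] array.
fftcVolumes <- function(x, inverse = FALSE) {
  d <- base::dim(x)
  f <- if (inverse) ifftc else fftc
  if (length(d) == 3) return(f(x))
  m <- matrix(x, prod(d[1:3]), prod(d[-(1:3)]))
  out <- matrix(complex(real = 0), nrow(m), ncol(m))
  for (j in seq_len(ncol(m))) out[, j] <- as.vector(f(array(m[, j], d[1:3])))
  array(out, d)
}

# Complex-exponential phase ramp that shifts a 3-D image by `shift` voxels
# (may be fractional) when multiplied into its centered k-space.
shiftRamp <- function(d, shift) {
  k1 <- centeredIndex(d[1]) / d[1]
  k2 <- centeredIndex(d[2]) / d[2]
  k3 <- centeredIndex(d[3]) / d[3]
  ph <- outer(outer(k1 * shift[1], k2 * shift[2], `+`), k3 * shift[3], `+`)
  exp(-2i * pi * ph)
}

# Shift a 3-D image by a (possibly subpixel) vector via its k-space phase.
shiftImage <- function(x, shift) {
  ifftc(fftc(x) * shiftRamp(dim(x), shift))
}
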