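# Log-linear diffusion tensor estimation and FA/MD scalar maps.

#' Fit the diffusion tensor by log-linear least squares
#'
#' Solves \eqn{\ln S = \ln S_0 - b\, g^T D\, g} per voxel with ordinary
#' least squares over the 7-parameter design (lnS0 plus the 6 unique tensor
#' components). Exact on noiseless data. Voxels with any nonpositive signal
#' are excluded from the fit mask.
#'
#' @param volumes numeric array [nx, ny, nz, nVolumes] of magnitude signal.
#' @param scheme a \code{\link{DiffusionScheme}} with >= 6 non-collinear
#'   directions and >= 1 b0 volume.
#' @param mask logical array of candidate voxels (default: all).
#' @return a \code{\link{TensorFit}}.
#' @export
fitTensor <- function(volumes, scheme, mask = NULL) {
  d <- dim(volumes)
  stopifnot2(length(d) == 4L, "volumes must be [nx, ny, nz, nVolumes]")
  b <- bValues(scheme); g <- bVectors(scheme)
  stopifnot2(length(b) == d[4], "scheme and volumes disagree on volume count")
  if (sum(b > 0) < 6L)
    stop("tensor fit needs at least 6 diffusion-weighted volumes", call. = FALSE)
  if (sum(b == 0) < 1L)
    stop("tensor fit needs at least one b0 volume", call. = FALSE)
  X <- cbind(1, -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  qrX <- qr(X)
  if (qrX$rank < 7L) {
    stop(sprintf(paste0("rank-deficient diffusion design (rank %d of 7): the ",
                        "direction set is collinear; directions:\n%s"),
                 qrX$rank,
                 paste(apply(round(g[, b > 0, drop = FALSE], 3), 2, paste,
                             collapse = ","), collapse = "; ")), call. = FALSE)
  }
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  nVox <- prod(d[1:3])
  sig <- matrix(volumes, nVox, d[4])
  ok <- as.vector(mask) & apply(sig > 0, 1, all)
  coefs <- matrix(NA_real_, nVox, 7)
  resid <- rep(NA_real_, nVox)
  if (any(ok)) {
    Ylog <- t(log(sig[ok, , drop = FALSE]))
    beta <- qr.coef(qrX, Ylog)
    res <- Ylog - X %*% beta
    coefs[ok, ] <- t(beta)
    resid[ok] <- sqrt(colMeans(res^2))
  }
  nExcluded <- sum(as.vector(mask) & !ok)
  if (nExcluded > 0)
    message(sprintf("fitTensor: %d masked voxels with nonpositive signal excluded",
                    nExcluded))
  Darr <- array(coefs[, 2:7], c(d[1:3], 6L))
  Darr[is.na(Darr)] <- 0
  lnS0 <- array(coefs[, 1], d[1:3]); lnS0[is.na(lnS0)] <- 0
  rr <- array(resid, d[1:3]); rr[is.na(rr)] <- 0
  new("TensorFit", D = Darr, lnS0 = lnS0,
      fitMask = array(ok, d[1:3]), residRms = rr)
}

#' FA and MD maps from a tensor fit
#'
#' Mean diffusivity is the eigenvalue mean; fractional anisotropy is
#' \eqn{FA = \sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert / \lVert\lambda\rVert}.
#' Negative eigenvalues (noise artefacts) are clamped to zero before FA and
#' flagged per voxel; an all-zero tensor gets FA = 0 by convention.
#'
#' @param fit a \code{\link{TensorFit}}.
#' @return a \code{\link{ScalarMaps}}.
#' @export
scalarMaps <- function(fit) {
  d <- dim(fit@D)[1:3]
  n <- prod(d)
  Dm <- matrix(fit@D, n, 6)
  fa <- numeric(n); md <- numeric(n); clamped <- logical(n)
  idx <- which(as.vector(fit@fitMask) | rowSums(abs(Dm)) > 0)
  for (i in idx) {
    M <- matrix(c(Dm[i, 1], Dm[i, 4], Dm[i, 5],
                  Dm[i, 4], Dm[i, 2], Dm[i, 6],
                  Dm[i, 5], Dm[i, 6], Dm[i, 3]), 3, 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    md[i] <- mean(ev)
    if (any(ev < 0)) { clamped[i] <- TRUE; ev <- pmax(ev, 0) }
    nrm <- sqrt(sum(ev^2))
    fa[i] <- if (nrm == 0) 0 else
      min(1, sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / nrm)
  }
  new("ScalarMaps", fa = array(fa, d), md = array(pmax(md, 0), d),
      clamped = array(clamped, d))
}

#' Ground-truth scalar maps of a phantom
#'
#' Convenience wrapper: eigen-decomposes the phantom's true tensor field.
#'
#' @param phantom a \code{\link{TensorPhantom}}.
#' @return a \code{\link{ScalarMaps}}.
#' @export
phantomScalarMaps <- function(phantom) {
  scalarMaps(new("TensorFit", D = phantom@D,
                 lnS0 = array(0, phantom@shape),
                 fitMask = phantom@mask,
                 residRms = array(0, phantom@shape)))
}
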