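# Synthetic multi-coil diffusion k-space simulator: tensor phantoms with
# white-matter-like tracts, smooth complex coil profiles, smooth object
# phase, complex Gaussian k-space noise, drift-induced shifts, and
# retrospective undersampling.

#' Build a tensor phantom
#'
#' An ellipsoidal "brain" with configurable regions: isotropic parenchyma,
#' one or two curved anisotropic tracts whose prolate tensor follows the
#' local tract tangent, and an isotropic high-diffusivity "ventricle". The
#' default diffusivities are literature-typical for fixed rodent tissue:
#' parenchyma 0.7e-3 mm^2/s, tract eigenvalues (1.7, 0.2, 0.2)e-3 mm^2/s,
#' ventricle 2.0e-3 mm^2/s.
#'
#' @param shape integer(3) grid size; >= 16 per axis recommended (>= 8
#'   accepted for small test problems).
#' @param dParenchyma,dVentricle isotropic diffusivities (mm^2/s).
#' @param tractEigen length-3 prolate tensor eigenvalues (mm^2/s).
#' @param nTracts 0, 1 or 2 curved tracts.
#' @param s0 baseline signal inside the mask.
#' @return a \code{\link{TensorPhantom}}.
#' @export
makePhantom <- function(shape = c(32L, 32L, 16L),
                        dParenchyma = 0.7e-3, dVentricle = 2.0e-3,
                        tractEigen = c(1.7e-3, 0.2e-3, 0.2e-3),
                        nTracts = 2L, s0 = 1) {
  shape <- as.integer(shape)
  stopifnot2(all(shape >= 8L), "each phantom dimension must be >= 8")
  stopifnot2(nTracts %in% 0:2, "nTracts must be 0, 1 or 2")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xs <- centeredIndex(nx); ys <- centeredIndex(ny); zs <- centeredIndex(nz)
  X <- array(rep(xs, times = ny * nz), shape)
  Y <- array(rep(rep(ys, each = nx), times = nz), shape)
  Z <- array(rep(zs, each = nx * ny), shape)
  ax <- 0.44 * nx; ay <- 0.44 * ny; az <- 0.42 * nz
  mask <- (X / ax)^2 + (Y / ay)^2 + (Z / az)^2 <= 1
  labels <- array(0L, shape)
  labels[mask] <- 1L
  D <- array(0, c(shape, 6L))
  isoD <- function(d) c(d, d, d, 0, 0, 0)
  idxPar <- which(mask)
  for (k in 1:6) {
    comp <- array(0, shape)
    comp[idxPar] <- isoD(dParenchyma)[k]
    D[, , , k] <- comp
  }
  setTensor <- function(D, vox, tens) {
    n <- prod(shape)
    for (k in 1:6) D[vox + (k - 1L) * n] <- tens[k]
    D
  }
  # ventricle: small central ellipsoid
  vent <- mask & ((X / (0.12 * nx))^2 + (Y / (0.12 * ny))^2 +
                  (Z / (0.25 * nz))^2 <= 1)
  D <- setTensor(D, which(vent), isoD(dVentricle))
  labels[vent] <- 3L
  # curved tracts: circular arcs in the x-y plane at fixed z band, prolate
  # tensor with the principal axis along the local tangent
  prolate <- function(tangent) {
    t1 <- tangent / sqrt(sum(tangent^2))
    # complete an orthonormal frame
    a <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t2 <- a - sum(a * t1) * t1; t2 <- t2 / sqrt(sum(t2^2))
    t3 <- c(t1[2] * t2[3] - t1[3] * t2[2],
            t1[3] * t2[1] - t1[1] * t2[3],
            t1[1] * t2[2] - t1[2] * t2[1])
    Dm <- tractEigen[1] * outer(t1, t1) + tractEigen[2] * outer(t2, t2) +
      tractEigen[3] * outer(t3, t3)
    c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
  }
  addArcTract <- function(D, labels, cx, cy, R, thetaLim, zc, tube) {
    th <- atan2(Y - cy, X - cx)
    rad <- sqrt((X - cx)^2 + (Y - cy)^2)
    sel <- mask & !vent & abs(rad - R) <= tube &
      th >= thetaLim[1] & th <= thetaLim[2] & abs(Z - zc) <= tube
    vox <- which(sel)
    if (length(vox) == 0) return(list(D = D, labels = labels))
    for (i in vox) {
      tang <- c(-sin(th[i]), cos(th[i]), 0)
      D <- setTensor(D, i, prolate(tang))
    }
    labels[sel] <- max(labels, 3L) + 1L
    list(D = D, labels = labels)
  }
  tube <- max(1.2, 0.06 * min(nx, ny))
  if (nTracts >= 1L) {
    res <- addArcTract(D, labels, cx = 0, cy = -0.5 * ay, R = 0.55 * ay,
                       thetaLim = c(0.25 * pi, 0.75 * pi), zc = 0, tube = tube)
    D <- res$D; labels <- res$labels
  }
  if (nTracts >= 2L) {
    res <- addArcTract(D, labels, cx = 0, cy = 0.55 * ay, R = 0.5 * ay,
                       thetaLim = c(-0.8 * pi, -0.2 * pi),
                       zc = round(0.2 * az), tube = tube)
    D <- res$D; labels <- res$labels
  }
  S0 <- array(0, shape)
  S0[mask] <- s0
  new("TensorPhantom", shape = shape, D = D, S0 = S0, mask = mask,
      labels = labels)
}

#' Noiseless diffusion-weighted signal volumes
#'
#' Mono-exponential tensor forward model
#' \eqn{S_v = S_0 \exp(-b_v\, g_v^T D\, g_v)} evaluated per voxel and volume.
#'
#' @param phantom a \code{\link{TensorPhantom}}.
#' @param scheme a \code{\link{DiffusionScheme}}.
#' @return numeric array [nx, ny, nz, nVolumes].
#' @export
dwiSignal <- function(phantom, scheme) {
  b <- bValues(scheme); g <- bVectors(scheme)
  shape <- phantom@shape
  n <- prod(shape)
  Dm <- matrix(phantom@D, n, 6)
  out <- array(0, c(shape, length(b)))
  s0 <- as.vector(phantom@S0)
  for (v in seq_along(b)) {
    if (b[v] == 0) { out[, , , v] <- phantom@S0; next }
    gv <- g[, v]
    q <- Dm[, 1] * gv[1]^2 + Dm[, 2] * gv[2]^2 + Dm[, 3] * gv[3]^2 +
      2 * (Dm[, 4] * gv[1] * gv[2] + Dm[, 5] * gv[1] * gv[3] +
           Dm[, 6] * gv[2] * gv[3])
    out[, , , v] <- array(s0 * exp(-b[v] * q), shape)
  }
  out
}

#' Smooth complex coil sensitivity profiles
#'
#' Each coil's magnitude is a broad Gaussian bump centred outside the FOV
#' edge (surface-coil-like) and its phase a low-order polynomial with small
#' seeded coefficients, so profiles are smooth and the sum of squares is
#' strictly positive everywhere.
#'
#' @param shape integer(3) grid.
#' @param nCoils number of receive channels (default 4).
#' @param seed integer seed.
#' @return a \code{\link{CoilProfiles}}.
#' @export
makeCoilProfiles <- function(shape, nCoils = 4L, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot2(nCoils >= 1L, "nCoils must be >= 1")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xs <- centeredIndex(nx) / nx; ys <- centeredIndex(ny) / ny
  zs <- centeredIndex(nz) / nz
  X <- array(rep(xs, times = ny * nz), shape)
  Y <- array(rep(rep(ys, each = nx), times = nz), shape)
  Z <- array(rep(zs, each = nx * ny), shape)
  ang <- 2 * pi * (seq_len(nCoils) - 1) / nCoils
  prof <- array(complex(real = 0), c(shape, nCoils))
  coefs <- withSeed(seed, matrix(runif(nCoils * 6, -1, 1), nCoils, 6))
  for (c in seq_len(nCoils)) {
    cx <- 0.75 * cos(ang[c]); cy <- 0.75 * sin(ang[c])
    mag <- 0.15 + exp(-(((X - cx)^2 + (Y - cy)^2) / (2 * 0.45^2) +
                        Z^2 / (2 * 0.6^2)))
    ph <- coefs[c, 1] + 1.5 * (coefs[c, 2] * X + coefs[c, 3] * Y +
                               coefs[c, 4] * Z) +
      1.0 * (coefs[c, 5] * X * Y + coefs[c, 6] * X * Z)
    prof[, , , c] <- mag * exp(1i * ph)
  }
  new("CoilProfiles", profiles = prof)
}

# Smooth polynomial object phase of a given total order (0 => zero phase).
objectPhase <- function(shape, order, seed, amplitude = 1.2) {
  if (order <= 0) return(array(0, shape))
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xs <- centeredIndex(nx) / nx; ys <- centeredIndex(ny) / ny
  zs <- centeredIndex(nz) / nz
  X <- array(rep(xs, times = ny * nz), shape)
  Y <- array(rep(rep(ys, each = nx), times = nz), shape)
  Z <- array(rep(zs, each = nx * ny), shape)
  terms <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
    if (i + j + k >= 1) terms[[length(terms) + 1L]] <- X^i * Y^j * Z^k
  cf <- withSeed(seed, runif(length(terms), -1, 1))
  ph <- array(0, shape)
  for (t in seq_along(terms)) ph <- ph + cf[t] * terms[[t]]
  amplitude * pi * ph / max(abs(ph))
}

#' Simulate multi-coil complex k-space from signal volumes
#'
#' Forms \eqn{X_{c,v} = F(s_c \cdot S_v \cdot e^{i\varphi}) + \varepsilon}
#' with the shared centred orthonormal FFT, a smooth polynomial object phase
#' of order \code{phaseOrder} (0 gives a real object, hence Hermitian
#' k-space), and i.i.d. complex Gaussian noise of std \code{noiseSigma} per
#' real/imaginary component.
#'
#' @param volumes numeric array [nx, ny, nz, nVolumes] of nonnegative signal.
#' @param coils a \code{\link{CoilProfiles}}.
#' @param scheme the \code{\link{DiffusionScheme}} the volumes follow.
#' @param phaseOrder polynomial order of the object phase (default 2).
#' @param noiseSigma complex-noise std per component (default 0; see the
#'   vignette for the peak-SNR rationale behind simulation defaults).
#' @param seed integer seed.
#' @param centerHalfwidths optional centre-block override for the grid.
#' @return a \code{\link{MultiCoilKSpace}}.
#' @export
simulateKspace <- function(volumes, coils, scheme, phaseOrder = 2L,
                           noiseSigma = 0, seed = 1L,
                           centerHalfwidths = NULL) {
  d <- dim(volumes)
  stopifnot2(length(d) == 4L, "volumes must be [nx, ny, nz, nVolumes]")
  stopifnot2(all(volumes >= 0), "signal volumes must be nonnegative")
  prof <- coilArray(coils)
  stopifnot2(identical(dim(prof)[1:3], d[1:3]),
             "coil profiles and volumes disagree on grid shape")
  nC <- dim(prof)[4]; nV <- d[4]
  grid <- if (is.null(centerHalfwidths))
    samplingGrid(d[1], d[2], d[3]) else
    samplingGrid(d[1], d[2], d[3], centerHalfwidths = centerHalfwidths)
  ph <- objectPhase(d[1:3], phaseOrder, seed + 7919L)
  eip <- exp(1i * ph)
  ks <- array(complex(real = 0), c(d[1:3], nC, nV))
  for (v in seq_len(nV)) {
    obj <- volumes[, , , v] * eip
    for (c in seq_len(nC)) ks[, , , c, v] <- fftc(prof[, , , c] * obj)
  }
  if (noiseSigma > 0) {
    n <- length(ks)
    noise <- withSeed(seed, complex(real = rnorm(n, sd = noiseSigma),
                                    imaginary = rnorm(n, sd = noiseSigma)))
    ks <- ks + array(noise, dim(ks))
  }
  new("MultiCoilKSpace", data = ks, grid = grid, scheme = scheme,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

#' Apply a progressive drift-induced spatial shift
#'
#' Emulates the registrable component of a slow resonance-frequency drift:
#' volume v is shifted by \code{totalShiftPx * v / (nVolumes - 1)} voxels
#' along \code{axis}, implemented as a linear phase ramp on its k-space so
#' sample magnitudes are untouched.
#'
#' @param kspace a \code{\link{MultiCoilKSpace}}.
#' @param totalShiftPx shift of the last volume, in voxels (|shift| < grid/4).
#' @param axis 1 (read), 2 (PE1) or 3 (PE2).
#' @return a shifted \code{\link{MultiCoilKSpace}}.
#' @export
applyDrift <- function(kspace, totalShiftPx, axis = 2L) {
  d <- dim(kspace@data)
  stopifnot2(abs(totalShiftPx) < d[axis] / 4,
             "total drift shift must stay below a quarter of the grid")
  if (totalShiftPx == 0) return(kspace)
  nV <- d[5]
  out <- kspace@data
  for (v in seq_len(nV)) {
    s <- numeric(3)
    s[axis] <- totalShiftPx * (v - 1) / (nV - 1)
    if (all(s == 0)) next
    ramp <- shiftRamp(d[1:3], s)
    for (c in seq_len(d[4])) out[, , , c, v] <- out[, , , c, v] * ramp
  }
  initialize(kspace, data = out)
}

#' Retrospectively undersample acquired k-space
#'
#' Zeroes every k-space sample whose PE-plane mask entry is 0; the mask is
#' replicated across coils and along the fully sampled readout axis.
#' Idempotent, and the identity for all-ones masks.
#'
#' @param kspace a \code{\link{MultiCoilKSpace}}.
#' @param maskSet a \code{\link{MaskSet}} on the same grid.
#' @return the undersampled \code{\link{MultiCoilKSpace}}.
#' @export
retrospectiveUndersample <- function(kspace, maskSet) {
  d <- dim(kspace@data)
  m <- maskArray(maskSet)
  if (!identical(dim(m)[1:2], d[2:3]) || dim(m)[3] != d[5])
    stop("mask set and k-space disagree on PE grid or volume count",
         call. = FALSE)
  out <- kspace@data
  for (v in seq_len(d[5])) {
    mv <- array(rep(m[, , v], each = d[1]), d[1:3])
    for (c in seq_len(d[4])) out[, , , c, v] <- out[, , , c, v] * mv
  }
  initialize(kspace, data = out)
}
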