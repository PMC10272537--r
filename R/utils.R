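# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All user-facing stochastic operations
# funnel through this, so a seed argument fully determines their output.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

# Centered frequency/space index along an axis of length n: DC at n %/% 2 + 1.
centeredIndex <- function(n) seq_len(n) - (n %/% 2L + 1L)

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Relative L2 difference, guarding the zero-reference case.
relDiff <- function(x, ref) {
  d <- sqrt(sum(Mod(x - ref)^2))
  r <- sqrt(sum(Mod(ref)^2))
  if (r == 0) d else d / r
}

# Gaussian smoothing matrix (n x n) with truncated, edge-renormalised kernel;
# applied along array dimensions for separable 3-D filtering.
gaussianSmoother <- function(n, sigma, radius = max(1L, ceiling(3 * sigma))) {
  taps <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  sm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - radius):(i + radius)
    keep <- j >= 1 & j <= n
    w <- taps[keep]
    sm[i, j[keep]] <- w / sum(w)
  }
  sm
}

# Apply an n_d x n_d matrix along dimension d of a 3-D array.
applyAlongDim <- function(x, mat, dim) {
  d <- base::dim(x)
  perm <- switch(dim, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- d[perm]
  y <- mat %*% matrix(xp, nrow = dp[1])
  y <- array(y, dp)
  aperm(y, order(perm))
}

# Separable 3-D Gaussian filter with edge renormalisation.
gaussianFilter3D <- function(x, sigma) {
  d <- base::dim(x)
  for (k in 1:3) x <- applyAlongDim(x, gaussianSmoother(d[k], sigma), k)
  x
}
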