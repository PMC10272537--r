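# Gaussian-kernel PCA: training, eigensystem oracle, preimage denoising.

# Independent dense oracle: double-centred Gaussian kernel eigensystem
# computed directly, without the package's training path.
kpcaOracle <- function(X, sigma) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  K <- exp(-D2 / (2 * sigma^2))
  H <- diag(n) - matrix(1 / n, n, n)
  eigen(H %*% K %*% H, symmetric = TRUE)
}

test_that("training eigensystem matches a dense brute-force decomposition", {
  sim <- smallSim(noiseSigma = 0.004)
  ms <- buildMaskSet(sim$grid, sim$scheme, af = 2, fsB0 = TRUE, seed = 3)
  prior <- extractLowRes(retrospectiveUndersample(sim$ks, ms), maskSet = ms)
  model <- trainKpca(prior, variant = "lrp", nTrain = 150L, seed = 7,
                     scheme = sim$scheme)
  oracle <- kpcaOracle(model@trainingMatrix, model@sigmaK)
  n <- nrow(model@trainingMatrix)
  for (j in seq_len(min(10, model@rank)))
    expect_lt(abs(model@eigvals[j] - oracle$values[j]) / oracle$values[1],
              1e-8)
  # eigenvalues nonincreasing, PSD within tolerance
  expect_true(all(diff(model@eigvals) <= 1e-12))
  expect_true(all(model@eigvals > -1e-10 * max(model@eigvals)))
  # projection coefficients are scaled eigenvectors (up to sign)
  for (j in seq_len(min(3, model@rank))) {
    a <- model@alphas[, j] * sqrt(oracle$values[j])
    v <- oracle$vectors[, j]
    expect_lt(min(sqrt(sum((a - v)^2)), sqrt(sum((a + v)^2))), 1e-6)
  }
})

test_that("trainKpca handles ranks, degenerate sets and kernel structure", {
  sim <- smallSim(noiseSigma = 0.004)
  ms <- buildMaskSet(sim$grid, sim$scheme, af = 2, fsB0 = TRUE, seed = 3)
  us <- retrospectiveUndersample(sim$ks, ms)
  prior <- extractLowRes(us, maskSet = ms)
  model <- trainKpca(prior, variant = "lrp", nTrain = 200L, seed = 5,
                     scheme = sim$scheme)
  expect_s4_class(model, "KPCAModel")
  expect_true(all(diff(model@eigvals) <= 1e-12))
  expect_gte(model@rank, 1L)
  expect_identical(ncol(model@trainingMatrix), nVolumes(sim$scheme))
  # composite variant doubles the signal length
  mc <- trainKpca(prior, variant = "composite", nTrain = 200L, seed = 5,
                  scheme = sim$scheme)
  expect_identical(ncol(mc@trainingMatrix), 2L * nVolumes(sim$scheme))
  # all-identical training vectors: raw kernel all ones -> degenerate error
  priorFlat <- prior
  priorFlat@lowresImages[] <- 1 + 0i
  expect_error(trainKpca(priorFlat, variant = "lrp", nTrain = 50L),
               "degenerate")
  # explicit rank is honoured
  m5 <- trainKpca(prior, variant = "lrp", rank = 5L, nTrain = 200L, seed = 5,
                  scheme = sim$scheme)
  expect_identical(m5@rank, 5L)
})

test_that("full-rank denoising is near the identity on training points", {
  set.seed(13)
  n <- 40; L <- 10
  X <- matrix(runif(n * L), n)
  model <- new("KPCAModel", trainingMatrix = X, variant = "magnitude",
               sigmaK = median(dist(X)), alphas = matrix(0, n, 1),
               eigvals = rep(0, n), rank = 1L,
               preimage = list(maxIter = 100L, tol = 1e-10),
               kRowMeans = rep(0, n), kTotMean = 0)
  # rebuild a full-rank model through the same kernel algebra
  D2 <- as.matrix(dist(X))^2
  sigma <- model@sigmaK
  K <- exp(-D2 / (2 * sigma^2))
  rm1 <- rowMeans(K); tm <- mean(K)
  Kc <- K - outer(rm1, rep(1, n)) - outer(rep(1, n), rm1) + tm
  es <- eigen(Kc, symmetric = TRUE)
  r <- sum(es$values > 1e-10 * es$values[1])
  model@alphas <- sweep(es$vectors[, 1:r, drop = FALSE], 2,
                        sqrt(es$values[1:r]), `/`)
  model@eigvals <- es$values
  model@rank <- as.integer(r)
  model@kRowMeans <- rm1; model@kTotMean <- tm
  den <- kpcaDenoise(model, X[1:5, , drop = FALSE])
  for (i in 1:5)
    expect_lt(sqrt(sum((den[i, ] - X[i, ])^2)) / sqrt(sum(X[i, ]^2)), 1e-3)
})

test_that("denoising pulls noisy series toward the clean manifold", {
  # training series from a smooth one-parameter family
  set.seed(17)
  n <- 200; L <- 12
  t0 <- runif(n)
  clean <- function(t) exp(-outer(t, seq(0.2, 2.4, length.out = L)))
  X <- clean(t0)
  D2 <- as.matrix(dist(X))^2
  sigma <- median(sqrt(D2[upper.tri(D2)]))
  K <- exp(-D2 / (2 * sigma^2))
  rm1 <- rowMeans(K); tm <- mean(K)
  Kc <- K - outer(rm1, rep(1, n)) - outer(rep(1, n), rm1) + tm
  es <- eigen(Kc, symmetric = TRUE)
  r <- which(cumsum(pmax(es$values, 0)) / sum(pmax(es$values, 0)) >= 0.99)[1]
  model <- new("KPCAModel", trainingMatrix = X, variant = "magnitude",
               sigmaK = sigma,
               alphas = sweep(es$vectors[, 1:r, drop = FALSE], 2,
                              sqrt(es$values[1:r]), `/`),
               eigvals = pmax(es$values, 0), rank = as.integer(r),
               preimage = list(maxIter = 100L, tol = 1e-8),
               kRowMeans = rm1, kTotMean = tm)
  probe <- clean(0.5)
  noisy <- probe + matrix(rnorm(L, sd = 0.05), 1)
  den <- kpcaDenoise(model, noisy)
  dNoisy <- sqrt(sum((noisy - probe)^2))
  dDen <- sqrt(sum((den - probe)^2))
  expect_lt(dDen, dNoisy)
})

test_that("rank-1 denoising keeps cluster members near their own centroid", {
  set.seed(19)
  L <- 8
  c1 <- rep(0, L); c2 <- rep(4, L)
  X <- rbind(matrix(rnorm(25 * L, 0, 0.1), ncol = L) +
               matrix(c1, 25, L, byrow = TRUE),
             matrix(rnorm(25 * L, 0, 0.1), ncol = L) +
               matrix(c2, 25, L, byrow = TRUE))
  D2 <- as.matrix(dist(X))^2
  sigma <- median(sqrt(D2[upper.tri(D2)]))
  K <- exp(-D2 / (2 * sigma^2))
  rm1 <- rowMeans(K); tm <- mean(K)
  Kc <- K - outer(rm1, rep(1, 50)) - outer(rep(1, 50), rm1) + tm
  es <- eigen(Kc, symmetric = TRUE)
  model <- new("KPCAModel", trainingMatrix = X, variant = "magnitude",
               sigmaK = sigma,
               alphas = matrix(es$vectors[, 1] / sqrt(es$values[1])),
               eigvals = pmax(es$values, 0), rank = 1L,
               preimage = list(maxIter = 100L, tol = 1e-8),
               kRowMeans = rm1, kTotMean = tm)
  den <- kpcaDenoise(model, X[c(3, 30), , drop = FALSE])
  d11 <- sqrt(sum((den[1, ] - c1)^2)); d12 <- sqrt(sum((den[1, ] - c2)^2))
  d22 <- sqrt(sum((den[2, ] - c2)^2)); d21 <- sqrt(sum((den[2, ] - c1)^2))
  expect_lt(d11, d12)
  expect_lt(d22, d21)
})
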