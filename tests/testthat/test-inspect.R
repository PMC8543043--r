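test_that("effective spectrum is the weighted component sum", {
  grid <- tinyGrid(2, 2)
  C <- cbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  comps <- spectralComponents(C, grid)
  expect_equal(effectiveSpectrum(comps, c(1, 0)), C[, 1])
  expect_equal(effectiveSpectrum(comps, c(0.3, 0.7)), c(0.3, 0, 0, 0.7))
  same <- spectralComponents(cbind(C[, 1], C[, 1]), grid)
  expect_equal(effectiveSpectrum(same, c(0.5, 0.5)), C[, 1])
  expect_error(effectiveSpectrum(comps, c(1, 0, 0)), "does not match")
})

test_that("noise variance is the reference-volume sample variance", {
  prot <- tinyProtocol(bs = c(0, 0, 500), TEs = c(80, 160))
  # reference volumes are the two (b = 0, TE = 80 ms) columns
  sig <- rbind(c(0.9, 1.1, 0.5, 0.4, 0.45, 0.2),
               c(1.0, 1.0, 0.5, 0.4, 0.45, 0.2))
  img <- imageData(sig, prot)
  v <- estimateNoiseVariance(img)
  expect_equal(v[1], stats::var(c(0.9, 1.1)))  # 0.02
  expect_equal(v[2], 1e-10)                    # constant -> floor, not zero
  # a single qualifying volume is an error pointing at the sigma override
  prot1 <- tinyProtocol(bs = c(0, 500), TEs = c(80, 160))
  img1 <- imageData(sig[, c(1, 3, 4, 6)], prot1)
  expect_error(estimateNoiseVariance(img1), "sigma")
})

test_that("noise variance estimate is consistent for sigma = 1/SNR", {
  set.seed(5)
  snr <- 100
  prot <- placentalProtocol(nB = 10, TEs = c(78, 150))
  N <- 2000
  sig <- matrix(1, N, nEncodings(prot))
  noisy <- addRicianNoise(sig, snr = snr, seed = 5)
  img <- imageData(noisy, prot)
  v <- estimateNoiseVariance(img)
  expect_equal(mean(v), 1 / snr^2, tolerance = 0.05)
})

test_that("initialisation ranks peaks by mass and pads when short", {
  grid <- makeDefaultGrid(c(10, 6))
  prot <- smallProtocol()
  K <- buildKernel(prot, grid)
  P <- gridSize(grid)
  # mean spectrum with two isolated deltas of mass 0.9 / 0.1
  F0 <- numeric(P); F0[8] <- 0.9; F0[45] <- 0.1
  sig <- matrix(as.numeric(K@values %*% F0), 3, nEncodings(prot), byrow = TRUE)
  img <- imageData(sig, prot)
  co1 <- initializeComponents(img, K, grid, M = 1)
  expect_equal(which.max(componentMatrix(co1)[, 1]), 8L)
  co2 <- initializeComponents(img, K, grid, M = 2)
  expect_equal(which.max(componentMatrix(co2)[, 2]), 45L)
  expect_warning(initializeComponents(img, K, grid, M = 4), "padding")
})

test_that("component update matches the explicit stacked NNLS oracle", {
  set.seed(41)
  grid <- tinyGrid(3, 2)
  prot <- tinyProtocol()
  K <- buildKernel(prot, grid)
  P <- gridSize(grid); Ns <- nEncodings(prot); N <- 3; M <- 2
  C <- matrix(stats::runif(P * M), P, M)
  Z <- matrix(stats::runif(N * M, 0.1, 0.9), N, M)
  sig <- matrix(stats::runif(N * Ns), N, Ns)
  for (wgt in list(NULL, stats::runif(N, 0.5, 2))) {
    img <- imageData(sig, prot, sigma2 = wgt)
    comps <- spectralComponents(C, grid)
    for (m in 1:M) {
      got <- updateComponent(m, img, K, comps, Z, sigma2 = wgt)
      # oracle: explicitly stacked system, one sqrt(w_n) z_nm K block per voxel
      w <- if (is.null(wgt)) rep(1, N) else 1 / wgt
      A <- do.call(rbind, lapply(1:N, function(n) sqrt(w[n]) * Z[n, m] * K@values))
      b <- unlist(lapply(1:N, function(n) {
        R <- sig[n, ] - K@values %*% (C[, -m, drop = FALSE] %*% Z[n, -m])
        sqrt(w[n]) * as.numeric(R)
      }))
      oracle <- pracma::lsqnonneg(A, b)$x
      objS <- function(F) sum((A %*% F - b)^2)
      expect_lt(abs(objS(got) - objS(oracle)), 1e-3)
      expect_equal(got, oracle, tolerance = 1e-4)
    }
  }
})

test_that("component update is homogeneous in the weights and flags unused components", {
  set.seed(42)
  grid <- tinyGrid(2, 2)
  prot <- tinyProtocol()
  K <- buildKernel(prot, grid)
  sig <- matrix(stats::runif(2 * nEncodings(prot)), 2)
  img <- imageData(sig, prot)
  comps <- spectralComponents(matrix(stats::runif(4), 4, 1), grid)
  Z <- matrix(c(0.4, 0.8), 2, 1)
  F1 <- updateComponent(1, img, K, comps, Z)
  F2 <- updateComponent(1, img, K, comps, 3 * Z)
  expect_equal(F2, F1 / 3, tolerance = 1e-8)
  expect_warning(Fu <- updateComponent(1, img, K, comps, 0 * Z), "zero weight")
  expect_equal(Fu, componentMatrix(comps)[, 1])
})

test_that("weight update matches a fine simplex grid search", {
  set.seed(43)
  grid <- tinyGrid(3, 2)
  prot <- tinyProtocol()
  K <- buildKernel(prot, grid)
  P <- gridSize(grid)
  for (rep in 1:4) {
    C <- matrix(stats::runif(P * 2), P, 2)
    comps <- spectralComponents(C, grid)
    ztrue <- stats::runif(1)
    S <- as.numeric(K@values %*% (C %*% c(ztrue, 1 - ztrue))) +
      stats::rnorm(nrow(K@values), 0, 0.05)
    z <- updateWeights(S, K, comps)
    expect_equal(sum(z), 1, tolerance = 1e-9)
    A <- K@values %*% C
    obj <- function(z1) sum((A %*% c(z1, 1 - z1) - S)^2)
    zs <- seq(0, 1, by = 1e-3)
    expect_lte(obj(z[1]), min(vapply(zs, obj, 0)) + 1e-3)
  }
})

test_that("weight update inverts noiseless mixtures exactly", {
  grid <- makeDefaultGrid(c(8, 4))
  prot <- smallProtocol()
  K <- buildKernel(prot, grid)
  P <- gridSize(grid)
  C <- matrix(0, P, 2); C[4, 1] <- 1; C[25, 2] <- 1
  comps <- spectralComponents(C, grid)
  S1 <- as.numeric(K@values %*% C[, 2])
  expect_equal(updateWeights(S1, K, comps), c(0, 1), tolerance = 1e-8)
  Smix <- as.numeric(K@values %*% (C %*% c(0.5, 0.5)))
  expect_equal(updateWeights(Smix, K, comps), c(0.5, 0.5), tolerance = 1e-6)
  # box-only mode: same solution lies inside the box here
  zb <- updateWeights(Smix, K, comps, simplex = FALSE)
  expect_equal(zb, c(0.5, 0.5), tolerance = 1e-4)
})

test_that("log-likelihood matches the closed-form normal density", {
  prot <- tinyProtocol()
  grid <- tinyGrid(2, 2)
  K <- buildKernel(prot, grid)
  Ns <- nEncodings(prot)
  C <- matrix(stats::runif(8), 4, 2)
  comps <- spectralComponents(C, grid)
  Z <- matrix(c(0.5, 0.5), 1)
  S <- as.numeric(K@values %*% (C %*% c(0.5, 0.5)))
  # zero residual
  img <- imageData(matrix(S, 1), prot, sigma2 = 0.04)
  expect_equal(logLikelihood(img, K, comps, Z),
               -Ns / 2 * log(2 * pi * 0.04))
  # known residual r in every entry
  r <- 0.1
  img2 <- imageData(matrix(S + r, 1), prot, sigma2 = 0.04)
  expect_equal(logLikelihood(img2, K, comps, Z),
               -Ns / 2 * log(2 * pi * 0.04) - Ns * r^2 / (2 * 0.04))
  # doubling sigma^2 changes the value by the closed-form amount
  img3 <- imageData(matrix(S + r, 1), prot, sigma2 = 0.08)
  expect_equal(logLikelihood(img3, K, comps, Z),
               logLikelihood(img2, K, comps, Z) -
                 Ns / 2 * log(2) + Ns * r^2 / (2 * 0.04) - Ns * r^2 / (2 * 0.08))
  imgNA <- imageData(matrix(S, 1), prot)
  expect_error(logLikelihood(imgNA, K, comps, Z), "variance")
})

test_that("InSpect inverts a noiseless two-component phantom quickly", {
  grid <- makeDefaultGrid(c(10, 6))
  prot <- smallProtocol()
  K <- buildKernel(prot, grid)
  P <- gridSize(grid)
  C <- matrix(0, P, 2); C[10, 1] <- 1; C[40, 2] <- 1
  # scale truth components to unit reference signal so the per-voxel
  # normalisation convention leaves weights identifiable
  for (m in 1:2) C[, m] <- C[, m] / (K@values %*% C[, m])[1]
  N <- 36
  W <- cbind(seq(0.1, 0.9, length.out = N))
  W <- cbind(W, 1 - W)
  sig <- W %*% t(K@values %*% C)
  img <- imageData(sig, prot, sigma2 = 1e-6)
  fit <- runInspect(img, grid, M = 2)
  expect_true(isConverged(fit))
  expect_lte(fit@iterations, 3)
  perm <- order(-apply(spectralWeights(fit), 2, function(x) cor(x, W[, 1])))
  expect_lt(max(abs(spectralWeights(fit)[, perm] - W)), 1e-2)
  expect_true(all(abs(rowSums(spectralWeights(fit)) - 1) < 1e-6))
})

test_that("M = 1 degenerates to a stacked spectrum with unit weights", {
  grid <- makeDefaultGrid(c(8, 4))
  prot <- smallProtocol()
  K <- buildKernel(prot, grid)
  F0 <- numeric(gridSize(grid)); F0[12] <- 1
  F0 <- F0 / (K@values %*% F0)[1]
  sig <- matrix(rep(as.numeric(K@values %*% F0), 5), 5, byrow = TRUE)
  img <- imageData(sig, prot, sigma2 = 1e-6)
  fit <- runInspect(img, grid, M = 1)
  expect_equal(unname(spectralWeights(fit)[, 1]), rep(1, 5))
  expect_equal(which.max(componentMatrix(fit)[, 1]), 12L)
})

test_that("joint fitting of concatenated scans equals fitting the stack", {
  grid <- makeDefaultGrid(c(6, 4))
  prot <- smallProtocol()
  ph <- makePhantom(shape = c(6, 6), grid = grid, protocol = prot)
  imgA <- simulatePhantomData(ph, snr = 200, seed = 1)
  imgB <- simulatePhantomData(ph, snr = 200, seed = 2)
  joint <- suppressWarnings(runInspect(list(imgA, imgB), grid, M = 2))
  expect_equal(nrow(spectralWeights(joint)), 72L)
  manual <- suppressWarnings(runInspect(concatenateImages(list(imgA, imgB)),
                                        grid, M = 2))
  expect_equal(spectralWeights(joint), spectralWeights(manual))
  expect_error(concatenateImages(list(imgA, imageData(imgA@signals[, 1:10],
    acquisitionProtocol(encodings(prot)[1:10, , drop = FALSE])))),
    "same acquisition protocol")
})

test_that("weight rows stay on the simplex and the likelihood ascends", {
  grid <- makeDefaultGrid(12)
  ph <- makePhantom(shape = c(10, 10), grid = grid, protocol = smallProtocol())
  for (snr in c(100, 400)) {
    img <- simulatePhantomData(ph, snr = snr, seed = snr)
    fit <- suppressWarnings(runInspect(img, grid, M = 4))
    Z <- spectralWeights(fit)
    expect_true(all(abs(rowSums(Z) - 1) < 1e-6))
    expect_true(all(Z >= -1e-12 & Z <= 1 + 1e-12))
    ll <- logLikTrace(fit)
    if (length(ll) > 1)
      expect_true(all(diff(ll) >= -1e-6 * pmax(1, abs(ll[-length(ll)]))))
  }
})
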