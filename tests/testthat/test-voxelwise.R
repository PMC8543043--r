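test_that("regularised inversion recovers exact single-point spectra", {
  grid <- tinyGrid(2, 2)
  prot <- tinyProtocol()
  K <- buildKernel(prot, grid)
  for (j in seq_len(gridSize(grid))) {
    F <- numeric(gridSize(grid)); F[j] <- 1
    S <- as.numeric(K@values %*% F)
    Fhat <- fitVoxelSpectrum(S, K, alpha = 0)
    expect_equal(Fhat, F, tolerance = 1e-6)
  }
})

test_that("Tikhonov-NNLS matches a brute-force lattice search", {
  set.seed(21)
  K <- matrix(stats::runif(15), 5, 3)
  S <- stats::runif(5)
  alpha <- 0.01
  obj <- function(F) sum((K %*% F - S)^2) + alpha * sum(F^2)
  Fhat <- fitVoxelSpectrum(S, K, alpha)
  # exhaustive non-negative grid search over a fine lattice
  fmax <- max(Fhat) * 2 + 0.5
  lat <- seq(0, fmax, length.out = 41)
  best <- Inf
  for (a in lat) for (b in lat) for (cc in lat)
    best <- min(best, obj(c(a, b, cc)))
  expect_lte(obj(Fhat), best + 1e-3)
})

test_that("penalty limits and degenerate inputs behave", {
  grid <- tinyGrid(2, 2)
  K <- buildKernel(tinyProtocol(), grid)
  F0 <- c(0.5, 0, 0.3, 0)
  S <- as.numeric(K@values %*% F0)
  # alpha -> infinity drives the solution to zero
  expect_lt(sum(fitVoxelSpectrum(S, K, alpha = 1e8)), 1e-4)
  expect_warning(Fz <- fitVoxelSpectrum(numeric(nrow(K@values)), K), "all-zero")
  expect_equal(Fz, numeric(4))
  # objective sanity bounds
  alpha <- 0.01
  obj <- function(F) sum((K@values %*% F - S)^2) + alpha * sum(F^2)
  Fhat <- fitVoxelSpectrum(S, K, alpha)
  expect_lte(obj(Fhat), obj(numeric(4)))
  Fun <- fitVoxelSpectrum(S, K, 0)
  expect_lte(obj(Fhat), sum((K@values %*% Fun - S)^2) + alpha * sum(Fun^2))
})

test_that("L-curve corner selection finds the corner and handles edge cases", {
  expect_equal(selectAlphaLcurve(NULL, NULL, 0.01), 0.01)
  expect_error(selectAlphaLcurve(NULL, NULL, c(0.1, -1, 1)), "positive")
  # a genuinely L-shaped problem: noisy overdetermined system
  set.seed(4)
  grid <- makeDefaultGrid(c(8, 4))
  K <- buildKernel(smallProtocol(), grid)
  F0 <- numeric(gridSize(grid)); F0[c(5, 20)] <- c(2, 1)
  S <- as.numeric(K@values %*% F0) + stats::rnorm(nrow(K@values), 0, 0.02)
  cand <- 10^seq(-6, 2, by = 1)
  a <- selectAlphaLcurve(S, K, cand)
  expect_true(a %in% cand)
  expect_true(a >= 1e-5 && a <= 1)   # corner is interior, not an extreme
  # collinear curve falls back to the median candidate with a warning
  Kid <- diag(3)
  expect_warning(am <- selectAlphaLcurve(rep(1e-14, 3), Kid, c(1, 2, 4, 8, 16)),
                 "degenerate")
  expect_equal(am, 4)
})

test_that("sROI integration returns normalised fractions", {
  expect_equal(integrateSROI(c(0.25, 0.75), c(FALSE, TRUE)), 0.75)
  expect_equal(integrateSROI(c(1, 2, 3), rep(TRUE, 3)), 1)
  expect_equal(integrateSROI(c(1, 2, 3), rep(FALSE, 3)), 0)
  expect_equal(integrateSROI(numeric(3), c(TRUE, FALSE, TRUE)), 0)
  expect_equal(integrateSROI(c(0.25, 0.75), c(FALSE, TRUE), normalize = FALSE),
               0.75)
  expect_error(integrateSROI(1:3, c(TRUE, FALSE)), "lengths differ")
  g <- spectralGrid(ADC = c(1, 2, 4), T2star = c(10, 20))
  m <- sroiFromRanges(g, list(ADC = c(1.5, 5)))
  expect_equal(m, gridPoints(g)[, "ADC"] >= 1.5)
})

test_that("voxelwise mapping is per-voxel independent and order-equivariant", {
  set.seed(31)
  grid <- tinyGrid(3, 2)
  prot <- tinyProtocol()
  K <- buildKernel(prot, grid)
  P <- gridSize(grid)
  N <- 7
  W <- matrix(stats::runif(N * P), N, P)
  sig <- W %*% t(K@values)
  img <- imageData(sig, prot)
  srois <- list(seq_len(P) <= 3, seq_len(P) > 3)
  res <- mapVoxelwise(img, K, alpha = 0.01, srois = srois)
  expect_identical(dim(res$fractions), c(7L, 2L))
  expect_true(all(abs(rowSums(res$fractions) - 1) < 1e-9))
  # permuting voxels permutes the output identically
  perm <- sample(N)
  res2 <- mapVoxelwise(imageData(sig[perm, ], prot), K, 0.01, srois)
  expect_equal(res2$fractions, res$fractions[perm, ])
  # compressed per-voxel solve agrees with the direct stacked solver
  for (n in 1:3) {
    Fdir <- fitVoxelSpectrum(sig[n, ], K, 0.01)
    expect_equal(integrateSROI(Fdir, srois[[1]]), res$fractions[n, 1],
                 tolerance = 1e-6)
  }
})

test_that("noiseless single-component voxels integrate to 1 in their sROI", {
  grid <- makeDefaultGrid(10)
  prot <- smallProtocol()
  K <- buildKernel(prot, grid)
  comps <- phantomComponents(grid, protocol = prot)
  srois <- truthSROIs(grid)
  for (m in 1:4) {
    S <- as.numeric(K@values %*% componentMatrix(comps)[, m])
    F <- fitVoxelSpectrum(S, K, alpha = 1e-6)
    expect_gt(integrateSROI(F, srois[[m]]), 0.99)
  }
})
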