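test_that("placental protocol has the documented structure", {
  prot <- placentalProtocol()
  enc <- encodings(prot)
  expect_equal(nrow(enc), 330L)
  expect_equal(length(unique(enc[, "b"])), 61L)   # 60 non-zero values + b = 0
  expect_equal(sum(enc[, "b"] == 0), 30L)         # six b = 0 per TE
  expect_equal(sort(unique(enc[, "TE"])), c(78, 114, 150, 186, 222) / 1000)
  expect_equal(range(enc[enc[, "b"] > 0, "b"]), c(5, 1600))
  for (te in unique(enc[, "TE"]))
    expect_equal(sum(enc[, "TE"] == te & enc[, "b"] == 0), 6L)
})

test_that("ground-truth components sit at the canonical modes", {
  grid <- makeDefaultGrid()
  prot <- placentalProtocol(nB = 10, TEs = c(78, 150, 222))
  comps <- phantomComponents(grid, protocol = prot)
  expect_equal(nComponents(comps), 4L)
  modes <- componentModes(comps)
  truth <- cbind(T2star = c(0.05, 0.06, 0.07, 0.08),
                 ADC = c(2e-4, 3e-3, 5e-2, 2e-1))
  for (i in 1:4) for (nm in c("T2star", "ADC")) {
    co <- gridCoords(grid)[[nm]]
    expect_equal(modes[i, nm], co[which.min(abs(log(co) - log(truth[i, nm])))])
  }
  # distinct locations
  expect_equal(nrow(unique(modes)), 4L)
  # default scaling: unit predicted signal at the reference encodings
  K <- buildKernel(prot, grid)
  ref <- encodings(prot)[, "b"] == 0 & encodings(prot)[, "TE"] == 0.078
  for (m in 1:4)
    expect_equal(mean((K@values %*% componentMatrix(comps)[, m])[ref]), 1)
  # mass scaling: each component integrates to 1
  cm <- phantomComponents(grid, scale = "mass")
  expect_equal(unname(colSums(componentMatrix(cm))), rep(1, 4))
  # a grid that excludes a mode is a named error
  small <- makeDefaultGrid(8, list(ADC = c(1e-4, 0.01), T2star = c(0.01, 0.3)))
  expect_error(phantomComponents(small, protocol = prot), "outside the grid")
})

test_that("weight layouts are valid simplex maps", {
  W <- phantomWeights(c(50, 50))
  expect_equal(nrow(W), 2500L)
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(unname(rowSums(W)), rep(1, 2500))
  expect_equal(phantomWeights(c(4, 4), "uniform"),
               matrix(0.25, 16, 4))
  Wb <- phantomWeights(c(10, 10), "blocks")
  expect_true(all(abs(rowSums(Wb) - 1) < 1e-12))
  Wr1 <- phantomWeights(c(5, 5), "random", seed = 9)
  Wr2 <- phantomWeights(c(5, 5), "random", seed = 9)
  expect_identical(Wr1, Wr2)
  expect_error(phantomWeights(c(5, 5), "swirl"), "arg")
})

test_that("simulated signals follow the kernel model and normalisation", {
  grid <- makeDefaultGrid(12)
  prot <- smallProtocol()
  ph <- makePhantom(shape = c(6, 6), grid = grid, protocol = prot)
  img <- simulateSignal(ph)
  enc <- encodings(prot)
  ref <- enc[, "b"] == min(enc[, "b"]) & enc[, "TE"] == min(enc[, "TE"])
  # per-voxel mean over reference volumes is exactly 1
  expect_equal(unname(rowMeans(signalMatrix(img)[, ref])), rep(1, 36))
  # a pure single-component voxel reproduces K F_m up to its normalisation
  K <- buildKernel(prot, grid)
  W <- spectralWeights(ph)
  n <- which.max(W[, 3])
  pred <- as.numeric(K@values %*% effectiveSpectrum(canonicalComponents(ph), W[n, ]))
  expect_equal(signalMatrix(img)[n, ], pred / mean(pred[ref]), tolerance = 1e-12)
  # strongest encoding is weaker than the weakest for every voxel
  hi <- which.max(enc[, "b"] + enc[, "TE"])
  expect_true(all(signalMatrix(img)[, hi] < signalMatrix(img)[, which(ref)[1]]))
})

test_that("Rician noise has the right law and is reproducible", {
  x <- matrix(seq(0, 1, length.out = 64), 8)
  expect_equal(addRicianNoise(x, snr = 1e9, seed = 1), x, tolerance = 1e-6)
  n1 <- addRicianNoise(x, snr = 50, seed = 3)
  n2 <- addRicianNoise(x, snr = 50, seed = 3)
  expect_identical(n1, n2)   # bit-identical for identical (seed, SNR)
  expect_false(identical(n1, addRicianNoise(x, snr = 50, seed = 4)))
  # zero signal gives Rayleigh draws with mean sigma * sqrt(pi/2)
  z <- addRicianNoise(matrix(0, 1e5, 1), snr = 10, seed = 7)
  expect_equal(mean(z), 0.1 * sqrt(pi / 2), tolerance = 0.01)
  # lower SNR has the larger noise floor on the same seed stream
  lo <- addRicianNoise(matrix(0, 1e4, 1), snr = 50, seed = 8)
  hi <- addRicianNoise(matrix(0, 1e4, 1), snr = 400, seed = 8)
  expect_gt(mean(lo), mean(hi))
})

test_that("Rician bias lifts the mean of low-SNR magnitudes", {
  grid <- makeDefaultGrid(10)
  ph <- makePhantom(shape = c(4, 4), grid = grid, protocol = smallProtocol())
  clean <- signalMatrix(simulateSignal(ph))
  acc <- 0
  for (s in 1:20) acc <- acc + signalMatrix(addRicianNoise(simulateSignal(ph),
                                                           snr = 20, seed = s))
  expect_gt(mean(acc / 20 - clean), 0)
})

test_that("voxelwise mode perturbation preserves positivity and the null case", {
  grid <- makeDefaultGrid(10)
  ph <- makePhantom(shape = c(5, 5), grid = grid, protocol = smallProtocol())
  ph0 <- perturbComponents(ph, sdADC = 0, sdT2 = 0, seed = 2)
  expect_equal(signalMatrix(simulateSignal(ph0)), signalMatrix(simulateSignal(ph)),
               tolerance = 1e-10)
  php <- perturbComponents(ph, sdADC = 0.1, sdT2 = 0.1, seed = 2)
  expect_length(php@modes, 4L)
  for (m in 1:4) {
    expect_true(all(php@modes[[m]] > 0))
    expect_equal(nrow(php@modes[[m]]), 25L)
  }
  # perturbed signals differ from the unperturbed ones but stay normalised
  imgp <- simulateSignal(php)
  expect_false(isTRUE(all.equal(signalMatrix(imgp),
                                signalMatrix(simulateSignal(ph)))))
  enc <- encodings(ph@protocol)
  ref <- enc[, "b"] == min(enc[, "b"]) & enc[, "TE"] == min(enc[, "TE"])
  expect_equal(unname(rowMeans(signalMatrix(imgp)[, ref])), rep(1, 25))
})
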