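## Synthetic diffusion-relaxometry phantom: four canonical T2*-ADC
## components with known voxelwise weights on a 2-D image, simulated through
## the placental-style protocol, unit-normalised and corrupted with Rician
## noise at a chosen SNR. Provides ground truth for all recovery tests.

# the four canonical (T2* s, ADC mm^2/s) modes used throughout the phantom,
# spanning slow/hindered to fast/perfusing environments
.phantomModes <- function() {
  cbind(T2star = c(0.05, 0.06, 0.07, 0.08),
        ADC    = c(2e-4, 3e-3, 5e-2, 2e-1))
}

#' Placental-style diffusion-relaxometry protocol
#'
#' 66 diffusion weightings - six b = 0 volumes plus `nB - 6` values
#' log-spaced over 5-1600 s/mm^2 - crossed with echo times
#' 78, 114, 150, 186, 222 ms, for 330 contrast encodings. Volumes are
#' ordered with TE outermost and b innermost.
#'
#' @param nB total number of b-values per TE (default 66, including the
#'   six b = 0).
#' @param TEs echo times in milliseconds.
#' @param bMax,bMin range of the non-zero b-values (s/mm^2).
#' @param nB0 number of b = 0 volumes per TE.
#' @return an [AcquisitionProtocol-class] (TE stored in seconds).
#' @export
placentalProtocol <- function(nB = 66L, TEs = c(78, 114, 150, 186, 222),
                              bMin = 5, bMax = 1600, nB0 = 6L) {
  stopifnot(nB > nB0)
  b <- c(rep(0, nB0), exp(seq(log(bMin), log(bMax), length.out = nB - nB0)))
  enc <- cbind(b = rep(b, times = length(TEs)),
               TE = rep(TEs, each = length(b)))
  acquisitionProtocol(enc, teUnit = "ms")
}

#' Ground-truth canonical components of the phantom
#'
#' Four delta spectra at fixed (T2*, ADC) modes of
#' (0.05 s, 2e-4), (0.06 s, 3e-3), (0.07 s, 5e-2) and
#' (0.08 s, 0.2 mm^2/s), each placed at the nearest grid point (log
#' distance). With `spread > 0` each component is instead a small
#' Gaussian blob (in log coordinates) around its mode.
#'
#' With `scale = "reference"` (default) each component is scaled so
#' its predicted signal at the protocol's reference encodings
#' (minimum b, minimum TE) equals 1. Every simplex-weighted mixture
#' then has reference signal exactly 1, so the per-voxel unit
#' normalisation of the simulated data is a no-op and the ground-truth
#' weights are exactly identifiable from normalised data. With
#' `scale = "mass"` each component instead integrates to 1 (weights
#' are then spectral-mass fractions, which per-voxel normalisation
#' distorts by each component's reference decay).
#'
#' @param grid a [SpectralGrid-class] with `ADC` and `T2star`
#'   dimensions whose ranges contain all four modes.
#' @param spread blob standard deviation in log10 grid units (0 =
#'   delta).
#' @param scale `"reference"` or `"mass"` (see Details).
#' @param protocol protocol used for reference scaling;
#'   [placentalProtocol()] if NULL.
#' @return a [SpectralComponents-class] with M = 4.
#' @export
phantomComponents <- function(grid, spread = 0,
                              scale = c("reference", "mass"),
                              protocol = NULL) {
  scale <- match.arg(scale)
  modes <- .phantomModes()
  co <- grid@coords
  for (i in seq_len(nrow(modes))) {
    for (nm in colnames(modes)) {
      if (modes[i, nm] < min(co[[nm]]) || modes[i, nm] > max(co[[nm]]))
        stop(sprintf("ground-truth component %d (%s = %g) lies outside the grid range [%g, %g]",
                     i, nm, modes[i, nm], min(co[[nm]]), max(co[[nm]])))
    }
  }
  pts <- gridPoints(grid)
  P <- nrow(pts)
  C <- matrix(0, P, nrow(modes))
  for (i in seq_len(nrow(modes))) {
    d2 <- rep(0, P)
    for (nm in colnames(modes))
      d2 <- d2 + (log10(pts[, nm]) - log10(modes[i, nm]))^2
    if (spread > 0) {
      C[, i] <- exp(-d2 / (2 * spread^2))
    } else {
      C[which.min(d2), i] <- 1
    }
    C[, i] <- C[, i] / sum(C[, i])
  }
  if (scale == "reference") {
    if (is.null(protocol)) protocol <- placentalProtocol()
    K <- buildKernel(protocol, grid)
    enc <- protocol@encodings
    sel <- rep(TRUE, nrow(enc))
    for (nm in colnames(enc)) sel <- sel & enc[, nm] == min(enc[, nm])
    for (i in seq_len(ncol(C)))
      C[, i] <- C[, i] / mean((K@values %*% C[, i])[sel])
  }
  colnames(C) <- paste0("F", seq_len(ncol(C)))
  spectralComponents(C, grid)
}

#' Ground-truth voxelwise weight layouts
#'
#' Deterministic (given the seed) weight maps for a 2-D phantom image.
#' Layouts:
#' \describe{
#'   \item{`diagonal`}{components 3 and 4 swap dominance across the
#'     image diagonal while components 1 and 2 vary smoothly along the
#'     axes - the configuration under which weight-map estimation shows
#'     a mild diagonal artifact at low SNR.}
#'   \item{`blocks`}{four quadrants, each dominated (weight 0.7) by one
#'     component.}
#'   \item{`uniform`}{all weights equal 1/M.}
#'   \item{`random`}{seeded Dirichlet(1) weights per voxel.}
#' }
#'
#' @param shape integer length-2 image dimensions (default c(50, 50)).
#' @param layout layout name.
#' @param M number of components (4 for `diagonal`/`blocks`).
#' @param seed integer seed (used by `random`).
#' @return N x M weight matrix with rows summing to 1; voxel n maps to
#'   image cell (row, col) in column-major order, matching
#'   `arrayInd(n, shape)`.
#' @export
phantomWeights <- function(shape = c(50L, 50L),
                           layout = c("diagonal", "blocks", "uniform", "random"),
                           M = 4L, seed = 1L) {
  layout <- match.arg(layout)
  shape <- as.integer(shape)
  N <- prod(shape)
  ij <- arrayInd(seq_len(N), shape)
  u <- (ij[, 1] - 0.5) / shape[1]
  v <- (ij[, 2] - 0.5) / shape[2]
  W <- switch(layout,
    diagonal = {
      if (M != 4L) stop("the 'diagonal' layout is defined for M = 4")
      upper <- v > u
      cbind(0.15 + 0.45 * u,
            0.15 + 0.45 * (1 - v),
            ifelse(upper, 0.75, 0.10),
            ifelse(upper, 0.10, 0.75))
    },
    blocks = {
      if (M != 4L) stop("the 'blocks' layout is defined for M = 4")
      quad <- 1L + (u >= 0.5) + 2L * (v >= 0.5)
      W <- matrix(0.1, N, 4)
      W[cbind(seq_len(N), quad)] <- 0.7
      W
    },
    uniform = matrix(1 / M, N, M),
    random = {
      set.seed(as.integer(seed))
      g <- matrix(stats::rexp(N * M), N, M)
      g
    })
  W / rowSums(W)
}

#' Assemble a phantom
#'
#' @param shape image dimensions.
#' @param layout weight layout (see [phantomWeights()]).
#' @param grid spectral grid; [makeDefaultGrid()] if NULL.
#' @param protocol acquisition protocol; [placentalProtocol()] if NULL.
#' @param spread component blob spread (0 = grid deltas).
#' @param seed seed recorded on the phantom and used by random layouts.
#' @return a [Phantom-class]
#' @export
makePhantom <- function(shape = c(50L, 50L), layout = "diagonal",
                        grid = NULL, protocol = NULL, spread = 0, seed = 1L) {
  if (is.null(grid)) grid <- makeDefaultGrid()
  if (is.null(protocol)) protocol <- placentalProtocol()
  comps <- phantomComponents(grid, spread = spread, protocol = protocol)
  W <- phantomWeights(shape, layout, M = nComponents(comps), seed = seed)
  new("Phantom", shape = as.integer(shape), weights = W, components = comps,
      protocol = protocol, snr = NA_real_, seed = as.numeric(seed),
      layout = layout, modes = list())
}

#' Simulate noiseless phantom signals
#'
#' Generates `S_n = K F(z_n)` per voxel, then normalises each voxel so
#' the mean of its minimum-b, minimum-TE volumes equals 1. For a
#' perturbed phantom (non-empty `modes`) the signal is computed from
#' the voxelwise component modes directly, off-grid.
#'
#' @param phantom a [Phantom-class].
#' @param kernel kernel registry name.
#' @return an [MRImageData-class] with noiseless signals (sigma2 NA).
#' @export
simulateSignal <- function(phantom, kernel = "separable-exponential") {
  enc <- phantom@protocol@encodings
  if (length(phantom@modes)) {
    # voxelwise-perturbed truth: each voxel has its own component modes
    N <- nrow(phantom@weights)
    M <- ncol(phantom@weights)
    sig <- matrix(0, N, nrow(enc))
    fun <- .getKernel(kernel)
    mass <- colSums(phantom@components@values)  # amplitude of each delta
    for (m in seq_len(M)) {
      km <- fun(enc, phantom@modes[[m]])     # Ns x N (grid points = voxels)
      sig <- sig + t(km) * (phantom@weights[, m] * mass[m])
    }
  } else {
    K <- buildKernel(phantom@protocol, phantom@components@grid, kernel = kernel)
    sig <- phantom@weights %*% t(K@values %*% phantom@components@values)
  }
  sel <- rep(TRUE, nrow(enc))
  for (nm in colnames(enc)) sel <- sel & enc[, nm] == min(enc[, nm])
  norm <- rowMeans(sig[, sel, drop = FALSE])
  sig <- sig / norm
  imageData(sig, phantom@protocol,
            voxelIndex = cbind(arrayInd(seq_len(nrow(sig)), phantom@shape), 1L),
            imageDim = c(phantom@shape, 1L),
            normalization = norm)
}

#' Add Rician noise
#'
#' Replaces each sample s with `sqrt((s + e1)^2 + e2^2)` where e1, e2
#' are independent zero-mean Gaussians with standard deviation
#' `sigma = 1/SNR`, the magnitude-MR noise model at unit-normalised
#' signal level. Reproducible for a fixed seed.
#'
#' @param x an [MRImageData-class] or plain numeric signal array.
#' @param snr signal-to-noise ratio (> 0).
#' @param seed integer seed.
#' @return same type as `x`, with noisy signals.
#' @export
addRicianNoise <- function(x, snr, seed = 1L) {
  stopifnot(snr > 0)
  sig <- if (is(x, "MRImageData")) x@signals else x
  sigma <- 1 / snr
  set.seed(as.integer(seed))
  e1 <- stats::rnorm(length(sig), 0, sigma)
  e2 <- stats::rnorm(length(sig), 0, sigma)
  noisy <- sqrt((sig + e1)^2 + e2^2)
  if (is(x, "MRImageData")) {
    x@signals <- matrix(noisy, nrow(sig), ncol(sig))
    x
  } else {
    out <- noisy
    dim(out) <- dim(sig)
    out
  }
}

#' Simulate a noisy phantom dataset in one call
#'
#' [simulateSignal()] followed by [addRicianNoise()] and per-voxel
#' noise-variance estimation from the reference volumes.
#'
#' @param phantom a [Phantom-class].
#' @param snr signal-to-noise ratio.
#' @param seed integer seed for the noise stream.
#' @param estimateSigma estimate per-voxel sigma^2 from the b = 0,
#'   minimum-TE volumes (default TRUE).
#' @return an [MRImageData-class].
#' @export
simulatePhantomData <- function(phantom, snr, seed = 1L, estimateSigma = TRUE) {
  img <- addRicianNoise(simulateSignal(phantom), snr = snr, seed = seed)
  if (estimateSigma) img <- withNoiseVariance(img)
  img
}

#' Voxelwise perturbation of the ground-truth component modes
#'
#' Robustness phantom: each voxel's ground-truth component (T2*, ADC)
#' modes are independently jittered with multiplicative log-normal
#' noise (so perturbed values stay positive), emulating biological
#' variation of the underlying spectra across the image. The signal is
#' then simulated from the voxelwise modes directly.
#'
#' @param phantom a [Phantom-class] with delta components.
#' @param sdADC,sdT2 fractional (coefficient-of-variation style)
#'   standard deviations of the multiplicative jitter; 0.1 = 10%.
#' @param seed integer seed.
#' @return a [Phantom-class] with per-voxel `modes` filled in.
#' @export
perturbComponents <- function(phantom, sdADC = 0.1, sdT2 = 0.1, seed = 1L) {
  stopifnot(sdADC >= 0, sdT2 >= 0)
  modes0 <- componentModes(phantom@components)
  N <- nrow(phantom@weights)
  set.seed(as.integer(seed))
  phantom@modes <- lapply(seq_len(nrow(modes0)), function(m) {
    cbind(T2star = modes0[m, "T2star"] *
            exp(stats::rnorm(N, 0, sdT2) - sdT2^2 / 2),
          ADC = modes0[m, "ADC"] *
            exp(stats::rnorm(N, 0, sdADC) - sdADC^2 / 2))
  })
  phantom@seed <- as.numeric(seed)
  phantom
}

#' Truth-based sROIs for the phantom
#'
#' Four rectangles in (T2*, ADC) space, each containing exactly one of
#' the phantom's ground-truth modes. The ADC boundaries are the
#' geometric midpoints between consecutive mode ADCs (the modes are
#' separated mainly along ADC); T2* is unconstrained. Integrating
#' voxelwise spectra over these regions yields the baseline fraction
#' maps comparable to the ground-truth weights.
#'
#' @param grid a [SpectralGrid-class].
#' @return list of 4 logical masks of length P.
#' @export
truthSROIs <- function(grid) {
  modes <- .phantomModes()
  adc <- modes[, "ADC"]
  cuts <- c(0, sqrt(adc[-length(adc)] * adc[-1]), Inf)
  lapply(seq_along(adc), function(i)
    sroiFromRanges(grid, list(ADC = c(cuts[i], cuts[i + 1]))))
}
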