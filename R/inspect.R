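## InSpect core: joint estimation of M canonical spectral components shared
## across the image and per-voxel mixture weights, by block-coordinate
## ascent on the Gaussian log-likelihood
##   sum_n log N(S_n; K F(z_n), sigma_n^2 I),   F(z_n) = sum_m z_nm F_m.
## Component updates are non-negative least squares; weight updates are
## simplex- (default) or box-constrained least squares.

#' Effective spectrum of a voxel
#'
#' The voxel's spectrum under the model is the weighted sum of the
#' canonical components, `F(z) = sum_m z_m F_m`.
#'
#' @param components a [SpectralComponents-class] (or P x M matrix).
#' @param z length-M weight vector.
#' @return numeric length-P spectrum.
#' @export
effectiveSpectrum <- function(components, z) {
  C <- if (is(components, "SpectralComponents")) components@values else components
  if (length(z) != ncol(C))
    stop(sprintf("weight length %d does not match M = %d", length(z), ncol(C)))
  as.numeric(C %*% z)
}

#' Estimate per-voxel noise variance from reference volumes
#'
#' Uses the empirical variance, per voxel, of the volumes acquired with
#' the minimum diffusion weighting and the minimum echo time (for the
#' placental protocol: the six b = 0 volumes at TE = 78 ms). Variances
#' are floored at a small positive epsilon so constant signals do not
#' produce a degenerate likelihood.
#'
#' @param image an [MRImageData-class].
#' @param floor minimum admissible variance.
#' @return numeric length-N vector of variances.
#' @export
estimateNoiseVariance <- function(image, floor = 1e-10) {
  enc <- image@protocol@encodings
  sel <- rep(TRUE, nrow(enc))
  for (nm in colnames(enc)) sel <- sel & enc[, nm] == min(enc[, nm])
  if (sum(sel) < 2L)
    stop("fewer than 2 volumes share the minimum encoding in every dimension; ",
         "supply the noise variance explicitly (sigma2 argument / --sigma flag)")
  v <- apply(image@signals[, sel, drop = FALSE], 1, stats::var)
  pmax(v, floor)
}

#' Attach estimated noise variances to an image
#'
#' @param image an [MRImageData-class].
#' @param sigma2 optional explicit variance (scalar or per voxel);
#'   estimated from the reference volumes when NULL.
#' @return the image with its `sigma2` slot filled.
#' @export
withNoiseVariance <- function(image, sigma2 = NULL) {
  if (is.null(sigma2)) sigma2 <- estimateNoiseVariance(image)
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, nrow(image@signals))
  image@sigma2 <- as.numeric(sigma2)
  validObject(image)
  image
}

## ---- initialisation -------------------------------------------------------

# Local maxima of a flat spectrum on an n-D grid: points whose value is
# strictly >= all neighbours within Chebyshev distance 1 and > 0.
.localMaxima <- function(F, dims) {
  P <- length(F)
  arr <- array(F, dim = rev(dims))  # last grid dimension fastest = first array axis
  nd <- length(dims)
  idx <- which(arr > 0)
  if (!length(idx)) return(integer(0))
  coords <- arrayInd(idx, dim(arr))
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  ismax <- rep(TRUE, length(idx))
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (d in seq_len(nd)) ok <- ok & nb[, d] >= 1 & nb[, d] <= dim(arr)[d]
    lin <- rep(NA_integer_, nrow(nb))
    if (any(ok)) {
      mult <- cumprod(c(1, dim(arr)[-nd]))
      lin[ok] <- 1L + as.integer((nb[ok, , drop = FALSE] - 1) %*% mult)
      ismax[ok] <- ismax[ok] & arr[idx[ok]] >= arr[lin[ok]]
    }
  }
  idx[ismax]  # flat indices into arr == flat spectrum indices
}

# Chebyshev distance between two flat grid indices
.chebDist <- function(i, j, dims) {
  a <- arrayInd(i, rev(dims)); b <- arrayInd(j, rev(dims))
  max(abs(a - b))
}

# flat indices of the 3^nd neighbourhood (incl. centre) of flat index i
.neighbourhood <- function(i, dims) {
  adim <- rev(dims)
  nd <- length(adim)
  ctr <- arrayInd(i, adim)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  nb <- sweep(offs, 2, as.integer(ctr), "+")
  ok <- rep(TRUE, nrow(nb))
  for (d in seq_len(nd)) ok <- ok & nb[, d] >= 1 & nb[, d] <= adim[d]
  mult <- cumprod(c(1, adim[-nd]))
  sort(1L + as.integer((nb[ok, , drop = FALSE] - 1) %*% mult))
}

#' Initialise canonical components from the mean spectrum
#'
#' Fits the mean signal across all voxels with the regularised
#' voxelwise inversion, finds local maxima of the resulting spectrum on
#' the grid, and builds one initial component from each of the M
#' largest well-separated peaks (a peak plus its immediate grid
#' neighbourhood, normalised to unit mass). Peaks are "separate" when
#' at least one non-maximal cell lies between them in every dimension
#' (Chebyshev distance >= 2); ties are broken by neighbourhood mass,
#' then by lowest flat grid index. If fewer than M separable peaks
#' exist, the remainder are delta spectra at the largest remaining grid
#' values (with a warning).
#'
#' @param image an [MRImageData-class].
#' @param K a [KernelMatrix-class].
#' @param grid the [SpectralGrid-class] (must be the kernel's grid).
#' @param M number of components.
#' @param alpha Tikhonov weight for the mean-spectrum fit. The default
#'   0 is deliberate: the mean signal across N voxels carries noise of
#'   order sigma/sqrt(N), and regularisation biases peak locations by
#'   smearing mass along the kernel's nearly collinear columns.
#' @return a [SpectralComponents-class] with M columns ordered by
#'   decreasing peak mass. Each column is a unit-sum peak shape
#'   rescaled so its predicted signal at the reference (minimum-b,
#'   minimum-TE) encodings equals the image's mean reference signal:
#'   for unit-normalised data every simplex-weighted mixture of the
#'   initial components then matches the per-voxel signal scale
#'   exactly, which removes a slow scale-against-weights ridge from the
#'   subsequent alternating optimisation. Component scale is free in
#'   later updates.
#' @export
initializeComponents <- function(image, K, grid, M, alpha = 0) {
  stopifnot(M >= 1)
  dims <- lengths(grid@coords)
  P <- prod(dims)
  meanS <- colMeans(image@signals)
  Fbar <- fitVoxelSpectrum(meanS, K, alpha)
  peaks <- .localMaxima(Fbar, dims)
  if (length(peaks)) {
    mass <- vapply(peaks, function(i) sum(Fbar[.neighbourhood(i, dims)]), 0)
    ord <- order(-mass, peaks)
    peaks <- peaks[ord]
    # greedy selection of separated peaks
    chosen <- integer(0)
    for (p in peaks) {
      if (length(chosen) == M) break
      if (all(vapply(chosen, function(q) .chebDist(p, q, dims) >= 2L, TRUE)))
        chosen <- c(chosen, p)
    }
  } else chosen <- integer(0)
  C <- matrix(0, P, M)
  for (m in seq_along(chosen)) {
    nb <- .neighbourhood(chosen[m], dims)
    C[nb, m] <- Fbar[nb]
    C[, m] <- C[, m] / sum(C[, m])
  }
  if (length(chosen) < M) {
    warning(sprintf("only %d separable peaks found; padding to M = %d with largest remaining grid values",
                    length(chosen), M))
    used <- unique(unlist(lapply(chosen, .neighbourhood, dims = dims)))
    cand <- setdiff(order(-Fbar), used)
    if (!length(cand)) cand <- order(-Fbar)
    for (m in seq.int(length(chosen) + 1L, M)) {
      C[cand[m - length(chosen)], m] <- 1
    }
  }
  # scale each component to the image's mean signal at the reference
  # (minimum) encodings, so initial mixtures start on the data scale
  enc <- image@protocol@encodings
  sel <- rep(TRUE, nrow(enc))
  for (nm in colnames(enc)) sel <- sel & enc[, nm] == min(enc[, nm])
  target <- mean(image@signals[, sel])
  for (m in seq_len(M)) {
    ref <- mean((K@values %*% C[, m])[sel])
    if (ref > 0 && target > 0) C[, m] <- C[, m] * target / ref
  }
  colnames(C) <- paste0("F", seq_len(M))
  spectralComponents(C, grid)
}

## ---- update steps ---------------------------------------------------------

#' Update one canonical component (NNLS step)
#'
#' With all weights and the other components held fixed, component m
#' minimises the stacked non-negative least-squares objective
#' `sum_n w_n || z_nm K F_m - (S_n - K sum_{m' != m} z_nm' F_m') ||^2`
#' with voxel weights `w_n = 1` (default) or `w_n = 1/sigma_n^2`. The
#' weighted form is the exact block maximiser of the Gaussian
#' log-likelihood and coincides with the unweighted one when the noise
#' variance is homogeneous. The problem is solved as one NNLS on the
#' normal-equation-compressed system with design `c K` and target
#' `(1/c) sum_n w_n z_nm R_n`, where `c = sqrt(sum_n w_n z_nm^2)` and
#' R_n the partial residuals - exactly equivalent to stacking the
#' `sqrt(w_n) z_nm`-scaled per-voxel blocks.
#'
#' @param m index of the component to update.
#' @param image an [MRImageData-class].
#' @param K a [KernelMatrix-class].
#' @param components current [SpectralComponents-class].
#' @param weights current N x M weight matrix.
#' @param sigma2 optional per-voxel noise variances; when supplied the
#'   voxel blocks are weighted by 1/sigma_n^2.
#' @return updated length-P spectrum for component m. If the component
#'   is unused (all z_nm = 0) it is returned unchanged with a warning.
#' @export
updateComponent <- function(m, image, K, components, weights, sigma2 = NULL) {
  Km <- K@values
  C <- components@values
  z <- weights[, m]
  w <- if (is.null(sigma2)) rep(1, length(z)) else 1 / sigma2
  c2 <- sum(w * z^2)
  if (c2 == 0) {
    warning(sprintf("component %d has zero weight everywhere; left unchanged", m))
    return(C[, m])
  }
  cc <- sqrt(c2)
  # sum_n w_n z_nm R_n = S' (w z_m) - K C_{-m} (Z_{-m}' (w z_m)), no voxel loop
  wz <- w * z
  t1 <- as.numeric(crossprod(image@signals, wz))          # length Ns
  others <- setdiff(seq_len(ncol(C)), m)
  if (length(others)) {
    ww <- as.numeric(crossprod(weights[, others, drop = FALSE], wz))
    t1 <- t1 - as.numeric(Km %*% (C[, others, drop = FALSE] %*% ww))
  }
  .nnls(cc * Km, t1 / cc)
}

#' Update the weights of one voxel
#'
#' Maximises the voxel's Gaussian log-likelihood over the weights with
#' the components fixed. Since the covariance is `sigma_n^2 I` this is
#' the constrained least-squares problem `min ||K C z - S_n||^2` over
#' the probability simplex (default) or the box `[0, 1]^M`.
#'
#' @param S length-Ns signal of the voxel.
#' @param K a [KernelMatrix-class].
#' @param components [SpectralComponents-class].
#' @param sigma2 voxel noise variance (does not affect the argmax; kept
#'   in the signature for interface symmetry with the likelihood).
#' @param simplex constrain weights to sum to 1 (default TRUE).
#' @return length-M weight vector.
#' @export
updateWeights <- function(S, K, components, sigma2 = NULL, simplex = TRUE) {
  A <- K@values %*% components@values   # Ns x M
  if (simplex) .simplexLsq(A, S) else .boxLsq(A, S)
}

# Vectorised weight sweep over all voxels. The Gram matrix A'A (A = K C)
# and all right-hand sides A'S_n are formed once; each voxel then runs
# the tiny M x M active-set solve.
.updateWeightsAll <- function(image, K, components, simplex = TRUE,
                              prev = NULL) {
  A <- K@values %*% components@values
  N <- nrow(image@signals)
  M <- ncol(A)
  Z <- matrix(0, N, M)
  if (M == 1L) {
    if (simplex) return(Z + 1)
    a2 <- sum(A^2)
    zhat <- as.numeric(image@signals %*% A) / max(a2, 1e-300)
    return(matrix(pmin(pmax(zhat, 0), 1), ncol = 1))
  }
  if (simplex) {
    G <- crossprod(A)
    AtS <- crossprod(A, t(image@signals))   # M x N
    for (n in seq_len(N))
      Z[n, ] <- .simplexActiveSet(G, AtS[, n])
  } else {
    for (n in seq_len(N))
      Z[n, ] <- .boxLsq(A, image@signals[n, ],
                        start = if (is.null(prev)) NULL else prev[n, ])
  }
  Z
}

#' Gaussian log-likelihood of the InSpect model
#'
#' `sum_n log N(S_n; K F(z_n), sigma_n^2 I)` - the sum over voxels of
#' the multivariate normal log-density of the signal about the model
#' prediction, with isotropic per-voxel variance.
#'
#' @param image an [MRImageData-class] with `sigma2` set.
#' @param K a [KernelMatrix-class].
#' @param components [SpectralComponents-class].
#' @param weights N x M weight matrix.
#' @return scalar log-likelihood.
#' @export
logLikelihood <- function(image, K, components, weights) {
  s2 <- image@sigma2
  if (any(is.na(s2)) || any(s2 <= 0))
    stop("noise variances must be set and positive; see withNoiseVariance()")
  pred <- weights %*% t(K@values %*% components@values)   # N x Ns
  rss <- rowSums((image@signals - pred)^2)
  Ns <- ncol(image@signals)
  sum(-Ns / 2 * log(2 * pi * s2) - rss / (2 * s2))
}

#' Initialise the voxelwise weights
#'
#' One weight sweep (see [updateWeights()]) against the initial
#' components.
#'
#' @inheritParams updateWeights
#' @param image an [MRImageData-class].
#' @return N x M weight matrix.
#' @export
initializeWeights <- function(image, K, components, simplex = TRUE) {
  .updateWeightsAll(image, K, components, simplex = simplex)
}

## ---- main driver ----------------------------------------------------------

#' Run the InSpect inference algorithm
#'
#' Alternates non-negative least-squares updates of the M canonical
#' spectral components with constrained least-squares updates of the
#' voxelwise weights, starting from mean-spectrum peak initialisation,
#' until the maximum absolute weight change drops below `tol` or
#' `maxIter` iterations are reached. Each block update cannot decrease
#' the Gaussian log-likelihood; a decrease beyond numerical tolerance
#' raises a warning with the iteration trace.
#'
#' A list of images (e.g. several scans sharing a protocol) is fitted
#' jointly by voxel concatenation, estimating one common component set
#' with per-voxel (hence per-scan) noise variances.
#'
#' @param image an [MRImageData-class], or a list of them to fit jointly.
#' @param grid a [SpectralGrid-class].
#' @param M number of canonical components (>= 1).
#' @param tol convergence tolerance on max |change in z| (default 1e-3).
#' @param maxIter maximum iterations (default 5).
#' @param simplex constrain each voxel's weights to the probability
#'   simplex (default). With `simplex = FALSE` weights are only box
#'   constrained to \[0, 1\] and the component/weight scale split is not
#'   identifiable; prefer the default for unit-normalised data.
#' @param sigma2 optional explicit noise variance (scalar or per-voxel);
#'   estimated from the minimum-encoding volumes when absent.
#' @param alphaInit Tikhonov weight of the initialisation fit.
#' @param kernel kernel registry name.
#' @param verbose print per-iteration progress.
#' @return an [InspectFit-class].
#' @examples
#' ph <- makePhantom(shape = c(8, 8), grid = makeDefaultGrid(8),
#'                   protocol = placentalProtocol(nB = 12, TEs = c(78, 150, 222)))
#' img <- addRicianNoise(simulateSignal(ph), snr = 400, seed = 1)
#' fit <- runInspect(img, makeDefaultGrid(8), M = 4)
#' fit
#' @export
runInspect <- function(image, grid, M, tol = 1e-3, maxIter = 5L,
                       simplex = TRUE, sigma2 = NULL, alphaInit = 0,
                       kernel = "separable-exponential", verbose = FALSE) {
  stopifnot(M >= 1, tol > 0, maxIter >= 1)
  if (is.list(image)) image <- concatenateImages(image)
  if (all(is.na(image@sigma2)) || !is.null(sigma2))
    image <- withNoiseVariance(image, sigma2)
  K <- buildKernel(image@protocol, grid, kernel = kernel)

  comps <- initializeComponents(image, K, grid, M, alpha = alphaInit)
  Z <- .updateWeightsAll(image, K, comps, simplex = simplex)

  llTrace <- numeric(0)
  dzTrace <- numeric(0)
  ll <- logLikelihood(image, K, comps, Z)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    # Gauss-Seidel over components: each update sees the ones before it
    for (m in seq_len(M))
      comps@values[, m] <- withCallingHandlers(
        updateComponent(m, image, K, comps, Z, sigma2 = image@sigma2),
        warning = function(w) {
          if (verbose) message(conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    Znew <- .updateWeightsAll(image, K, comps, simplex = simplex, prev = Z)
    dz <- max(abs(Znew - Z))
    Z <- Znew
    llNew <- logLikelihood(image, K, comps, Z)
    if (llNew < ll - 1e-6 * max(1, abs(ll)))
      warning(sprintf(
        "log-likelihood decreased at iteration %d (%.6g -> %.6g); trace: %s",
        it, ll, llNew, paste(signif(c(llTrace, ll, llNew), 8), collapse = ", ")))
    ll <- llNew
    llTrace <- c(llTrace, ll)
    dzTrace <- c(dzTrace, dz)
    if (verbose)
      message(sprintf("iteration %d: max |dz| = %.3e, logLik = %.6g", it, dz, ll))
    if (dz < tol) { converged <- TRUE; break }
  }
  new("InspectFit", components = comps, weights = Z,
      logLik = ll, logLikTrace = llTrace, deltaTrace = dzTrace,
      iterations = it, converged = converged,
      config = list(M = M, tol = tol, maxIter = maxIter, simplex = simplex,
                    kernel = kernel, alphaInit = alphaInit))
}

#' Concatenate images for joint fitting
#'
#' Stacks the masked voxels of several scans that share an acquisition
#' protocol, preserving per-voxel noise variances, so one common set of
#' canonical components can be estimated across all of them.
#'
#' @param images list of [MRImageData-class] objects with identical
#'   protocols.
#' @return a single [MRImageData-class].
#' @export
concatenateImages <- function(images) {
  stopifnot(length(images) >= 1)
  enc0 <- images[[1]]@protocol@encodings
  for (im in images[-1])
    if (!isTRUE(all.equal(im@protocol@encodings, enc0)))
      stop("all images must share the same acquisition protocol")
  imageData(do.call(rbind, lapply(images, function(i) i@signals)),
            images[[1]]@protocol,
            sigma2 = unlist(lapply(images, function(i) i@sigma2)),
            voxelIndex = do.call(rbind, lapply(images, function(i) i@voxelIndex)),
            imageDim = images[[1]]@imageDim,
            normalization = unlist(lapply(images, function(i) i@normalization)))
}
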