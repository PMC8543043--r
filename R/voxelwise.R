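## Voxelwise baseline: per-voxel Tikhonov-regularised NNLS inversion of the
## discretised Fredholm problem, followed by numerical integration over
## spectral regions of interest (sROIs). This is the standard spectrum
## mapping pipeline that InSpect is benchmarked against.

#' Regularised non-negative spectrum inversion for one voxel
#'
#' Solves `argmin_{F >= 0} ||K F - S||^2 + alpha ||F||^2` by NNLS on the
#' stacked system `[K; sqrt(alpha) I]` vs `[S; 0]`, which is exactly
#' equivalent to the penalised objective.
#'
#' @param S numeric length-Ns signal vector.
#' @param K a [KernelMatrix-class] or plain Ns x P matrix.
#' @param alpha non-negative Tikhonov weight (0.01 is a typical L-curve
#'   choice for unit-normalised diffusion-relaxometry data).
#' @return numeric length-P non-negative spectrum. An all-zero signal
#'   returns the zero spectrum with a warning.
#' @seealso [selectAlphaLcurve()], [integrateSROI()], [mapVoxelwise()]
#' @export
fitVoxelSpectrum <- function(S, K, alpha = 0.01) {
  Km <- if (is(K, "KernelMatrix")) K@values else K
  .assertFinite(S, "signal")
  if (alpha < 0) stop("alpha must be non-negative")
  P <- ncol(Km)
  if (length(S) != nrow(Km))
    stop(sprintf("signal length %d does not match kernel rows %d",
                 length(S), nrow(Km)))
  if (all(S == 0)) {
    warning("all-zero signal: returning zero spectrum")
    return(numeric(P))
  }
  if (alpha > 0) {
    A <- rbind(Km, diag(sqrt(alpha), P))
    b <- c(S, numeric(P))
  } else {
    A <- Km
    b <- S
  }
  .nnls(A, b)
}

#' L-curve selection of the Tikhonov weight
#'
#' Fits the voxel spectrum at each candidate alpha, forms the L-curve
#' `(log ||K F - S||, log ||F||)`, and returns the candidate at maximum
#' curvature (the corner). A degenerate (collinear) curve falls back to
#' the median candidate with a warning.
#'
#' @param S signal vector.
#' @param K kernel matrix.
#' @param candidateAlphas numeric vector of positive candidates; a
#'   singleton is returned as-is.
#' @return the selected alpha (one of the candidates).
#' @export
selectAlphaLcurve <- function(S, K, candidateAlphas) {
  if (any(candidateAlphas <= 0)) stop("candidate alphas must be positive")
  if (length(candidateAlphas) == 1L) return(candidateAlphas)
  if (length(candidateAlphas) < 3L)
    stop("need at least 3 candidates (or exactly 1) for L-curve selection")
  Km <- if (is(K, "KernelMatrix")) K@values else K
  a <- sort(candidateAlphas)
  rho <- eta <- numeric(length(a))
  for (i in seq_along(a)) {
    F <- fitVoxelSpectrum(S, Km, a[i])
    rho[i] <- log(max(sqrt(sum((Km %*% F - S)^2)), 1e-300))
    eta[i] <- log(max(sqrt(sum(F^2)), 1e-300))
  }
  # curvature of the parametric curve (rho(a), eta(a)) by central differences
  n <- length(a)
  kappa <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    d1r <- (rho[i + 1] - rho[i - 1]) / 2
    d1e <- (eta[i + 1] - eta[i - 1]) / 2
    d2r <- rho[i + 1] - 2 * rho[i] + rho[i - 1]
    d2e <- eta[i + 1] - 2 * eta[i] + eta[i - 1]
    denom <- (d1r^2 + d1e^2)^1.5
    kappa[i] <- if (denom > 0) (d1r * d2e - d2r * d1e) / denom else 0
  }
  if (all(is.na(kappa) | abs(kappa) < 1e-10)) {
    warning("degenerate L-curve (collinear points): returning median candidate")
    return(a[ceiling(n / 2)])
  }
  a[which.max(kappa)]
}

#' Build an sROI mask from per-dimension ranges
#'
#' A spectral region of interest is a logical mask of length P over the
#' grid. Ranges are inclusive; dimensions omitted from `ranges` are
#' unconstrained.
#'
#' @param grid a [SpectralGrid-class].
#' @param ranges named list of `c(min, max)` per spectral dimension.
#' @return logical vector of length P in the grid's flattening order.
#' @export
sroiFromRanges <- function(grid, ranges) {
  pts <- gridPoints(grid)
  keep <- rep(TRUE, nrow(pts))
  for (nm in names(ranges)) {
    if (!nm %in% colnames(pts))
      stop(sprintf("grid has no dimension '%s'", nm))
    r <- ranges[[nm]]
    keep <- keep & pts[, nm] >= r[1] & pts[, nm] <= r[2]
  }
  keep
}

#' Integrate a spectrum over an sROI
#'
#' Numerically integrates (sums) the spectrum over the masked grid
#' points and normalises by the total spectral mass, giving the signal
#' fraction attributed to the region.
#'
#' @param F numeric length-P non-negative spectrum.
#' @param sroi logical length-P mask.
#' @param normalize if FALSE return the raw masked sum instead of the
#'   fraction.
#' @return scalar fraction in \[0, 1\] (0 if the spectrum has no mass).
#' @export
integrateSROI <- function(F, sroi, normalize = TRUE) {
  if (length(F) != length(sroi))
    stop("spectrum and sROI mask lengths differ")
  masked <- sum(F[sroi])
  if (!normalize) return(masked)
  total <- sum(F)
  if (total <= 0) return(0)
  masked / total
}

#' Voxelwise spectrum inversion and sROI integration over an image
#'
#' Runs [fitVoxelSpectrum()] independently in every masked voxel and
#' integrates each voxel's spectrum over each sROI. Per-voxel warnings
#' (e.g. all-zero signals) are collected into a log attribute rather
#' than aborting the image.
#'
#' @param image an [MRImageData-class].
#' @param K a [KernelMatrix-class] matching the image protocol.
#' @param alpha Tikhonov weight.
#' @param srois list of logical sROI masks (length P each).
#' @param keepSpectra if TRUE also return the P x N spectrum matrix.
#' @return list with `fractions` (N x n_sroi matrix), `raw` (unnormalised
#'   integrals), optionally `spectra`, and attribute `"log"` holding
#'   per-voxel warnings.
#' @export
mapVoxelwise <- function(image, K, alpha = 0.01, srois, keepSpectra = FALSE) {
  Km <- K@values
  P <- ncol(Km)
  sig <- image@signals
  N <- nrow(sig)
  srois <- if (is.list(srois)) srois else list(srois)
  for (s in srois) if (length(s) != P) stop("sROI mask length must equal P")
  fr <- raw <- matrix(NA_real_, N, length(srois))
  spectra <- if (keepSpectra) matrix(NA_real_, P, N) else NULL
  logbook <- character(0)

  # shared Cholesky compression of the stacked system: the normal matrix
  # K'K + alpha I is SPD for alpha > 0, so each voxel reduces to a P x P NNLS
  R <- if (alpha > 0) .cholCompress(crossprod(Km) + diag(alpha, P)) else NULL
  for (n in seq_len(N)) {
    S <- sig[n, ]
    F <- withCallingHandlers(
      {
        if (all(S == 0)) {
          warning("all-zero signal: returning zero spectrum")
          numeric(P)
        } else if (!is.null(R)) {
          d <- backsolve(R, crossprod(Km, S), transpose = TRUE)
          .nnls(R, d)
        } else {
          fitVoxelSpectrum(S, Km, alpha)
        }
      },
      warning = function(w) {
        logbook <<- c(logbook, sprintf("voxel %d: %s", n, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    for (j in seq_along(srois)) {
      fr[n, j] <- integrateSROI(F, srois[[j]])
      raw[n, j] <- integrateSROI(F, srois[[j]], normalize = FALSE)
    }
    if (keepSpectra) spectra[, n] <- F
  }
  out <- list(fractions = fr, raw = raw)
  if (keepSpectra) out$spectra <- spectra
  attr(out, "log") <- logbook
  out
}
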