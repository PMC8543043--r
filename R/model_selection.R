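## BIC-guided selection of the number of canonical spectral components.

#' Bayesian information criterion for an InSpect fit
#'
#' `BIC = k log(n) - 2 logLik` with `n = N Ns` observations and, under
#' the default simplex weight constraint, `k = (M - 1) N + M P` free
#' parameters (M - 1 free weights per voxel plus M spectra of P grid
#' values each). With the box-only constraint all M weights per voxel
#' are free and `k = M N + M P`. The log-likelihood is the value at the
#' last iteration of the inference algorithm. Noise variances are
#' estimated outside the likelihood maximisation and are not counted.
#'
#' @param fit an [InspectFit-class].
#' @param image the [MRImageData-class] the fit was run on.
#' @return a [ModelScore-class].
#' @export
computeBIC <- function(fit, image) {
  M <- ncol(fit@weights)
  N <- nrow(fit@weights)
  P <- nrow(fit@components@values)
  Ns <- ncol(image@signals)
  simplex <- isTRUE(fit@config$simplex)
  k <- if (simplex) (M - 1L) * N + M * P else M * N + M * P
  nObs <- as.numeric(N) * Ns
  ll <- fit@logLik
  new("ModelScore", M = as.integer(M), k = as.integer(k), nObs = nObs,
      logLik = ll, bic = k * log(nObs) - 2 * ll)
}

#' Select the number of components by BIC
#'
#' Runs [runInspect()] for each candidate M and scores each converged
#' fit with [computeBIC()]. The minimum-BIC M best explains the data in
#' the information-theoretic sense, but the full table is returned
#' because interpretability or prior knowledge may favour another
#' choice; treat the minimum as advisory. Failures for individual M are
#' recorded and selection proceeds over the successes.
#'
#' @param image an [MRImageData-class] (or list for joint fitting).
#' @param grid a [SpectralGrid-class].
#' @param MRange integer vector of candidate component counts.
#' @param keepFits return the fitted models as well.
#' @param ... further arguments to [runInspect()] (tol, maxIter,
#'   simplex, sigma2, ...).
#' @return list with `bestM`, `scores` (data.frame with columns M, k,
#'   nObs, logLik, bic, error), and optionally `fits`.
#' @export
selectM <- function(image, grid, MRange, keepFits = FALSE, ...) {
  stopifnot(length(MRange) >= 1)
  MRange <- as.integer(MRange)
  rows <- vector("list", length(MRange))
  fits <- if (keepFits) vector("list", length(MRange)) else NULL
  for (i in seq_along(MRange)) {
    M <- MRange[i]
    res <- tryCatch({
      fit <- suppressWarnings(runInspect(image, grid, M = M, ...))
      sc <- computeBIC(fit, if (is.list(image)) concatenateImages(image) else image)
      if (keepFits) fits[[i]] <- fit
      data.frame(M = M, k = sc@k, nObs = sc@nObs, logLik = sc@logLik,
                 bic = sc@bic, error = NA_character_)
    }, error = function(e) {
      data.frame(M = M, k = NA_integer_, nObs = NA_real_, logLik = NA_real_,
                 bic = NA_real_, error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  scores <- do.call(rbind, rows)
  ok <- !is.na(scores$bic)
  if (!any(ok)) stop("InSpect failed for every candidate M")
  bestM <- scores$M[ok][which.min(scores$bic[ok])]
  out <- list(bestM = bestM, scores = scores)
  if (keepFits) out$fits <- fits
  out
}
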