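#' @import methods
NULL

#' AcquisitionProtocol: the set of MR contrast encodings
#'
#' An acquisition protocol is an ordered table of Ns contrast encodings,
#' one per acquired volume. Each encoding is a vector of experimental
#' parameters, e.g. the diffusion weighting `b` (s/mm^2) and echo time
#' `TE` (seconds, internally). The protocol defines the rows of the
#' discretised kernel matrix.
#'
#' @slot encodings numeric matrix, Ns x n_dims, with named columns
#'   (e.g. `"b"`, `"TE"`). Row order matches the 4th axis of the image.
#'
#' @seealso [acquisitionProtocol()], [buildKernel()], [placentalProtocol()]
#' @export
setClass("AcquisitionProtocol",
  representation(encodings = "matrix"),
  validity = function(object) {
    enc <- object@encodings
    if (nrow(enc) < 1L) return("protocol must contain at least one encoding")
    if (is.null(colnames(enc)) || any(!nzchar(colnames(enc))))
      return("encoding dimensions must be named (matrix column names)")
    if (anyDuplicated(colnames(enc)))
      return("encoding dimension names must be unique")
    if (!all(is.finite(enc))) return("all encoding values must be finite")
    if ("b" %in% colnames(enc) && any(enc[, "b"] < 0))
      return("b-values must be non-negative")
    if ("TE" %in% colnames(enc) && any(enc[, "TE"] <= 0))
      return("echo times must be strictly positive")
    TRUE
  }
)

#' SpectralGrid: discretised spectral-domain coordinates
#'
#' A rectangular grid over the spectral domain omega (by default
#' ADC x T2*), given as one strictly increasing, strictly positive
#' coordinate vector per dimension. Spectra are stored as flat vectors
#' of length P = prod(lengths); the flattening order is fixed with the
#' *last* dimension varying fastest (see [gridPoints()]).
#'
#' @slot coords named list of numeric coordinate vectors; default names
#'   are `"ADC"` (mm^2/s) and `"T2star"` (seconds).
#'
#' @seealso [spectralGrid()], [makeDefaultGrid()], [gridPoints()]
#' @export
setClass("SpectralGrid",
  representation(coords = "list"),
  validity = function(object) {
    co <- object@coords
    if (length(co) < 1L) return("grid needs at least one dimension")
    if (is.null(names(co)) || any(!nzchar(names(co))))
      return("grid dimensions must be named")
    for (nm in names(co)) {
      v <- co[[nm]]
      if (!is.numeric(v) || length(v) < 1L)
        return(sprintf("dimension '%s' must be a numeric vector", nm))
      if (any(!is.finite(v)) || any(v <= 0))
        return(sprintf("dimension '%s' must be finite and strictly positive", nm))
      if (length(v) > 1L && any(diff(v) <= 0))
        return(sprintf("dimension '%s' must be strictly increasing", nm))
    }
    TRUE
  }
)

#' KernelMatrix: discretised kernel linking spectrum to signal
#'
#' The Ns x P matrix K with entries K[i, j] = K(t_i, omega_j), so that a
#' voxel's noiseless signal is S = K F for a flat spectrum F on the
#' grid. Rows follow the protocol's encoding order, columns the grid's
#' flattening order.
#'
#' @slot values numeric Ns x P matrix; entries in (0, 1] for the
#'   separable exponential kernel.
#' @slot protocol the [AcquisitionProtocol-class] that produced the rows.
#' @slot grid the [SpectralGrid-class] that produced the columns.
#' @slot kernelName name of the kernel family used (registry key).
#'
#' @seealso [buildKernel()], [evaluateKernel()]
#' @export
setClass("KernelMatrix",
  representation(values = "matrix", protocol = "AcquisitionProtocol",
                 grid = "SpectralGrid", kernelName = "character"),
  validity = function(object) {
    if (nrow(object@values) != nrow(object@protocol@encodings))
      return("kernel row count must equal number of protocol encodings")
    if (ncol(object@values) != prod(lengths(object@grid@coords)))
      return("kernel column count must equal number of grid points")
    if (!all(is.finite(object@values)))
      return("kernel values must be finite")
    TRUE
  }
)

#' SpectralComponents: a set of canonical spectral components
#'
#' M non-negative spectra F_1..F_M on a shared [SpectralGrid-class],
#' stored as the columns of a P x M matrix. Component order is the
#' initialisation order and is stable across updates.
#'
#' @slot values numeric P x M matrix of non-negative spectrum values.
#' @slot grid the shared [SpectralGrid-class].
#'
#' @seealso [spectralComponents()], [phantomComponents()],
#'   [effectiveSpectrum()]
#' @export
setClass("SpectralComponents",
  representation(values = "matrix", grid = "SpectralGrid"),
  validity = function(object) {
    if (ncol(object@values) < 1L) return("need at least one component (M >= 1)")
    if (nrow(object@values) != prod(lengths(object@grid@coords)))
      return("component length must equal number of grid points")
    if (!all(is.finite(object@values)) || any(object@values < 0))
      return("component spectra must be finite and non-negative")
    TRUE
  }
)

#' MRImageData: masked voxel signals plus noise bookkeeping
#'
#' The N masked voxel signals of an acquisition, as an N x Ns matrix
#' (voxels x encodings), together with per-voxel noise variances, the
#' protocol, the voxel-to-image coordinate lookup and the per-voxel
#' normalisation factors applied on load.
#'
#' @slot signals numeric N x Ns matrix of (typically unit-normalised)
#'   signals.
#' @slot sigma2 numeric length-N vector of per-voxel noise variances
#'   (NA until estimated; see [estimateNoiseVariance()]).
#' @slot protocol the [AcquisitionProtocol-class] shared by all voxels.
#' @slot voxelIndex integer matrix N x 3 of (i, j, k) image coordinates
#'   of the masked voxels, in the row order of `signals`.
#' @slot imageDim integer length-3 spatial image dimensions.
#' @slot normalization numeric length-N per-voxel scale divided out of
#'   the raw signals (1 if none).
#'
#' @seealso [imageData()], [readImageData()], [simulateSignal()]
#' @export
setClass("MRImageData",
  representation(signals = "matrix", sigma2 = "numeric",
                 protocol = "AcquisitionProtocol",
                 voxelIndex = "matrix", imageDim = "integer",
                 normalization = "numeric"),
  validity = function(object) {
    N <- nrow(object@signals)
    if (N < 1L) return("image must contain at least one masked voxel")
    if (ncol(object@signals) != nrow(object@protocol@encodings))
      return("signal column count must equal number of protocol encodings")
    if (!all(is.finite(object@signals)))
      return("signals must be finite (mask out NaN voxels before loading)")
    if (length(object@sigma2) != N)
      return("sigma2 must have one entry per voxel")
    if (any(!is.na(object@sigma2) & object@sigma2 <= 0))
      return("noise variances must be strictly positive")
    if (nrow(object@voxelIndex) != N)
      return("voxelIndex must have one row per voxel")
    if (length(object@normalization) != N)
      return("normalization must have one entry per voxel")
    TRUE
  }
)

#' InspectFit: the converged InSpect model
#'
#' Result of [runInspect()]: the canonical spectral components, the
#' N x M voxelwise weight map, the Gaussian log-likelihood, and the
#' convergence trace (max absolute weight change and log-likelihood per
#' iteration).
#'
#' @slot components [SpectralComponents-class] at the final iteration.
#' @slot weights numeric N x M weight matrix z.
#' @slot logLik final log-likelihood.
#' @slot logLikTrace per-iteration log-likelihood.
#' @slot deltaTrace per-iteration max |change in z|.
#' @slot iterations iterations actually run.
#' @slot converged whether the weight-change tolerance was met.
#' @slot config list echoing the fit configuration (M, tol, maxIter,
#'   simplex, seed if any).
#'
#' @seealso [runInspect()], [computeBIC()]
#' @export
setClass("InspectFit",
  representation(components = "SpectralComponents", weights = "matrix",
                 logLik = "numeric", logLikTrace = "numeric",
                 deltaTrace = "numeric", iterations = "integer",
                 converged = "logical", config = "list"),
  validity = function(object) {
    if (ncol(object@weights) != ncol(object@components@values))
      return("weight columns must match number of components")
    if (!is.finite(object@logLik)) return("log-likelihood must be finite")
    if (any(object@weights < -1e-9) || any(object@weights > 1 + 1e-9))
      return("weights must lie in [0, 1]")
    TRUE
  }
)

#' ModelScore: BIC bookkeeping for one choice of M
#'
#' @slot M number of canonical spectral components.
#' @slot k parameter count, (M-1)N + M P under the simplex constraint.
#' @slot nObs observation count N Ns.
#' @slot logLik maximised log-likelihood at the last iteration.
#' @slot bic k log(nObs) - 2 logLik.
#'
#' @seealso [computeBIC()], [selectM()]
#' @export
setClass("ModelScore",
  representation(M = "integer", k = "integer", nObs = "numeric",
                 logLik = "numeric", bic = "numeric"),
  validity = function(object) {
    if (object@k < 1L) return("parameter count must be at least 1")
    if (!isTRUE(all.equal(object@bic,
                          object@k * log(object@nObs) - 2 * object@logLik)))
      return("bic must equal k*log(nObs) - 2*logLik")
    TRUE
  }
)

#' Phantom: synthetic ground truth for the diffusion-relaxometry study
#'
#' Ground-truth canonical components and voxelwise weights on a regular
#' 2-D image, plus the protocol and grid used to simulate from them.
#' When `modes` is non-empty the components are voxelwise-perturbed
#' (see [perturbComponents()]) and `modes[[m]]` holds the per-voxel
#' (ADC, T2*) mode locations of component m.
#'
#' @slot shape integer length-2 image dimensions (default 50 x 50).
#' @slot weights numeric N x M ground-truth weight matrix (rows sum 1).
#' @slot components ground-truth [SpectralComponents-class].
#' @slot protocol the [AcquisitionProtocol-class] used for simulation.
#' @slot snr nominal signal-to-noise ratio (sigma = 1/SNR after unit
#'   normalisation); NA until noise is added.
#' @slot seed integer seed recorded for reproducibility (NA if unset).
#' @slot layout name of the weight layout generator used.
#' @slot modes list of per-voxel component mode matrices (empty unless
#'   perturbed).
#'
#' @seealso [makePhantom()], [simulateSignal()], [addRicianNoise()]
#' @export
setClass("Phantom",
  representation(shape = "integer", weights = "matrix",
                 components = "SpectralComponents",
                 protocol = "AcquisitionProtocol",
                 snr = "numeric", seed = "numeric", layout = "character",
                 modes = "list"),
  validity = function(object) {
    if (any(object@shape < 1L)) return("image dimensions must be >= 1")
    if (nrow(object@weights) != prod(object@shape))
      return("weight rows must equal number of voxels")
    if (any(object@weights < 0) || any(object@weights > 1))
      return("ground-truth weights must lie in [0, 1]")
    if (any(abs(rowSums(object@weights) - 1) > 1e-8))
      return("ground-truth weights must sum to 1 in every voxel")
    TRUE
  }
)
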