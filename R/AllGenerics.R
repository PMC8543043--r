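#' Construct an AcquisitionProtocol
#'
#' @param encodings numeric matrix or data.frame, one row per acquired
#'   volume, named columns (e.g. `b`, `TE`).
#' @param teUnit unit of any `TE` column: `"s"` (default) or `"ms"`.
#'   Milliseconds are converted to seconds on construction; all internal
#'   computation uses seconds.
#' @return an [AcquisitionProtocol-class]
#' @examples
#' p <- acquisitionProtocol(data.frame(b = c(0, 500), TE = c(78, 78)),
#'                          teUnit = "ms")
#' nEncodings(p)
#' @export
acquisitionProtocol <- function(encodings, teUnit = c("s", "ms")) {
  teUnit <- match.arg(teUnit)
  enc <- as.matrix(as.data.frame(encodings))
  storage.mode(enc) <- "double"
  if (teUnit == "ms" && "TE" %in% colnames(enc))
    enc[, "TE"] <- enc[, "TE"] / 1000
  new("AcquisitionProtocol", encodings = enc)
}

#' Construct a SpectralGrid
#'
#' @param ... named numeric coordinate vectors, one per spectral
#'   dimension, each strictly increasing and positive, e.g.
#'   `spectralGrid(ADC = c(1e-4, 1e-3), T2star = c(0.05, 0.1))`.
#' @return a [SpectralGrid-class]
#' @export
spectralGrid <- function(...) {
  co <- list(...)
  if (length(co) == 1L && is.list(co[[1]]) && is.null(names(co)))
    co <- co[[1]]
  new("SpectralGrid", coords = lapply(co, as.numeric))
}

#' Construct a SpectralComponents set
#'
#' @param values numeric P x M matrix (or length-P vector for M = 1) of
#'   non-negative spectrum values in the grid's flattening order.
#' @param grid the shared [SpectralGrid-class].
#' @return a [SpectralComponents-class]
#' @export
spectralComponents <- function(values, grid) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  new("SpectralComponents", values = values, grid = grid)
}

#' Construct an MRImageData object from a signal matrix
#'
#' @param signals numeric N x Ns matrix, masked voxels by encodings.
#' @param protocol an [AcquisitionProtocol-class] with Ns encodings.
#' @param sigma2 optional per-voxel noise variances (default NA,
#'   estimate later with [estimateNoiseVariance()]).
#' @param voxelIndex optional integer N x 3 voxel coordinates; defaults
#'   to a linear 1-D indexing.
#' @param imageDim optional length-3 spatial dimensions.
#' @param normalization optional per-voxel scale already divided out.
#' @return an [MRImageData-class]
#' @export
imageData <- function(signals, protocol, sigma2 = NULL, voxelIndex = NULL,
                      imageDim = NULL, normalization = NULL) {
  signals <- as.matrix(signals)
  N <- nrow(signals)
  if (is.null(sigma2)) sigma2 <- rep(NA_real_, N)
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, N)
  if (is.null(voxelIndex))
    voxelIndex <- cbind(seq_len(N), 1L, 1L)
  storage.mode(voxelIndex) <- "integer"
  if (is.null(imageDim)) imageDim <- c(N, 1L, 1L)
  if (is.null(normalization)) normalization <- rep(1, N)
  new("MRImageData", signals = signals, sigma2 = as.numeric(sigma2),
      protocol = protocol, voxelIndex = voxelIndex,
      imageDim = as.integer(imageDim), normalization = as.numeric(normalization))
}

## ---- accessors ------------------------------------------------------------

#' @describeIn acquisitionProtocol number of encodings Ns
#' @param object,x an object of the documented class
#' @export
setGeneric("nEncodings", function(object) standardGeneric("nEncodings"))

#' @export
setMethod("nEncodings", "AcquisitionProtocol",
          function(object) nrow(object@encodings))

#' @export
setMethod("nEncodings", "MRImageData",
          function(object) nrow(object@protocol@encodings))

#' Encoding table of a protocol
#' @param object an [AcquisitionProtocol-class] or [MRImageData-class]
#' @return numeric matrix Ns x n_dims
#' @export
setGeneric("encodings", function(object) standardGeneric("encodings"))

#' @export
setMethod("encodings", "AcquisitionProtocol", function(object) object@encodings)

#' @export
setMethod("encodings", "MRImageData", function(object) object@protocol@encodings)

#' Number of points P of a spectral grid
#' @param object a [SpectralGrid-class] (or object carrying one)
#' @export
setGeneric("gridSize", function(object) standardGeneric("gridSize"))

#' @export
setMethod("gridSize", "SpectralGrid",
          function(object) prod(lengths(object@coords)))

#' Per-dimension coordinate vectors of a grid
#' @param object a [SpectralGrid-class]
#' @export
setGeneric("gridCoords", function(object) standardGeneric("gridCoords"))

#' @export
setMethod("gridCoords", "SpectralGrid", function(object) object@coords)

#' Flattened grid-point coordinates
#'
#' Returns the P x n_dims matrix of grid-point coordinates in the fixed
#' flattening order: the *last* grid dimension varies fastest. All flat
#' spectra, kernel columns and sROI masks use this order.
#'
#' @param object a [SpectralGrid-class]
#' @return numeric matrix with one named column per dimension
#' @export
setGeneric("gridPoints", function(object) standardGeneric("gridPoints"))

#' @export
setMethod("gridPoints", "SpectralGrid", function(object) {
  co <- object@coords
  # expand.grid varies the first factor fastest; feed dimensions reversed
  g <- do.call(expand.grid, c(rev(co), KEEP.OUT.ATTRS = FALSE))
  as.matrix(g[, rev(seq_along(co)), drop = FALSE])
})

#' Number of masked voxels N
#' @param object an [MRImageData-class], [InspectFit-class] or [Phantom-class]
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))

#' @export
setMethod("nVoxels", "MRImageData", function(object) nrow(object@signals))

#' @export
setMethod("nVoxels", "Phantom", function(object) nrow(object@weights))

#' Signal matrix of an image (N x Ns)
#' @param object an [MRImageData-class]
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @export
setMethod("signalMatrix", "MRImageData", function(object) object@signals)

#' Per-voxel noise variances
#' @param object an [MRImageData-class]
#' @export
setGeneric("noiseVariance", function(object) standardGeneric("noiseVariance"))

#' @export
setMethod("noiseVariance", "MRImageData", function(object) object@sigma2)

#' Number of canonical spectral components M
#' @param object a [SpectralComponents-class] or [InspectFit-class]
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @export
setMethod("nComponents", "SpectralComponents",
          function(object) ncol(object@values))

#' @export
setMethod("nComponents", "InspectFit",
          function(object) ncol(object@components@values))

#' Component spectra as a P x M matrix
#' @param object a [SpectralComponents-class], [InspectFit-class] or
#'   [Phantom-class]
#' @export
setGeneric("componentMatrix", function(object) standardGeneric("componentMatrix"))

#' @export
setMethod("componentMatrix", "SpectralComponents", function(object) object@values)

#' @export
setMethod("componentMatrix", "InspectFit",
          function(object) object@components@values)

#' @export
setMethod("componentMatrix", "Phantom",
          function(object) object@components@values)

#' Canonical components of a fit or phantom
#' @param object an [InspectFit-class] or [Phantom-class]
#' @export
setGeneric("canonicalComponents",
           function(object) standardGeneric("canonicalComponents"))

#' @export
setMethod("canonicalComponents", "InspectFit", function(object) object@components)

#' @export
setMethod("canonicalComponents", "Phantom", function(object) object@components)

#' Voxelwise weight map (N x M)
#' @param object an [InspectFit-class] or [Phantom-class]
#' @export
setGeneric("spectralWeights", function(object) standardGeneric("spectralWeights"))

#' @export
setMethod("spectralWeights", "InspectFit", function(object) object@weights)

#' @export
setMethod("spectralWeights", "Phantom", function(object) object@weights)

#' Convergence flag of a fit
#' @param object an [InspectFit-class]
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @export
setMethod("isConverged", "InspectFit", function(object) object@converged)

#' Per-iteration log-likelihood trace
#' @param object an [InspectFit-class]
#' @export
setGeneric("logLikTrace", function(object) standardGeneric("logLikTrace"))

#' @export
setMethod("logLikTrace", "InspectFit", function(object) object@logLikTrace)

## ---- show methods ---------------------------------------------------------

setMethod("show", "AcquisitionProtocol", function(object) {
  enc <- object@encodings
  cat("AcquisitionProtocol:", nrow(enc), "encodings,",
      paste(colnames(enc), collapse = " x "), "\n")
  for (nm in colnames(enc))
    cat(sprintf("  %s: %d unique values in [%g, %g]\n", nm,
                length(unique(enc[, nm])), min(enc[, nm]), max(enc[, nm])))
})

setMethod("show", "SpectralGrid", function(object) {
  co <- object@coords
  cat("SpectralGrid:", paste(lengths(co), collapse = " x "),
      sprintf("(P = %d points)\n", prod(lengths(co))))
  for (nm in names(co))
    cat(sprintf("  %s: [%g, %g]\n", nm, min(co[[nm]]), max(co[[nm]])))
})

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix '%s': %d encodings x %d grid points\n",
              object@kernelName, nrow(object@values), ncol(object@values)))
})

setMethod("show", "SpectralComponents", function(object) {
  cat(sprintf("SpectralComponents: M = %d on a %s grid\n",
              ncol(object@values),
              paste(lengths(object@grid@coords), collapse = " x ")))
  modes <- componentModes(object)
  for (m in seq_len(ncol(object@values)))
    cat(sprintf("  F%d: mode at (%s), mass %.4g\n", m,
                paste(sprintf("%s=%.4g", colnames(modes), modes[m, ]),
                      collapse = ", "),
                sum(object@values[, m])))
})

setMethod("show", "MRImageData", function(object) {
  cat(sprintf("MRImageData: %d voxels x %d encodings\n",
              nrow(object@signals), ncol(object@signals)))
  cat(sprintf("  noise variance: %s\n",
              if (all(is.na(object@sigma2))) "not yet estimated"
              else sprintf("median %.3g", stats::median(object@sigma2, na.rm = TRUE))))
})

setMethod("show", "InspectFit", function(object) {
  cat(sprintf("InspectFit: M = %d, %d voxels\n",
              ncol(object@weights), nrow(object@weights)))
  cat(sprintf("  %s after %d iteration(s); final max |dz| = %.2e\n",
              if (object@converged) "converged" else "not converged",
              object@iterations,
              if (length(object@deltaTrace)) utils::tail(object@deltaTrace, 1) else NA))
  cat(sprintf("  log-likelihood: %.6g\n", object@logLik))
})

setMethod("show", "ModelScore", function(object) {
  cat(sprintf("ModelScore: M = %d, k = %d, n = %g, logLik = %.6g, BIC = %.6g\n",
              object@M, object@k, object@nObs, object@logLik, object@bic))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %s image, M = %d components, layout '%s'\n",
              paste(object@shape, collapse = " x "),
              ncol(object@weights), object@layout))
  if (length(object@modes))
    cat("  component modes perturbed voxelwise\n")
})
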