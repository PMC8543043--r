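## File input/output: NIfTI volumes and masks (via RNifti), TSV protocols,
## JSON sROIs, and the standard output bundle of a fit (weight-map NIfTIs,
## component CSV, fit-report JSON). Internal computation is double
## precision; maps are written float32, the imaging convention.

#' Read / write an acquisition protocol TSV
#'
#' The protocol file is tab-separated with a header row naming the
#' encoding dimensions (`b` in s/mm^2, `TE` in ms) and one row per
#' volume, in the order of the 4th NIfTI axis.
#'
#' @param path TSV file path.
#' @return an [AcquisitionProtocol-class] (TE converted to seconds).
#' @export
readProtocol <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  acquisitionProtocol(df, teUnit = if ("TE" %in% names(df)) "ms" else "s")
}

#' @rdname readProtocol
#' @param protocol an [AcquisitionProtocol-class]
#' @export
writeProtocol <- function(protocol, path) {
  enc <- protocol@encodings
  df <- as.data.frame(enc)
  if ("TE" %in% names(df)) df$TE <- df$TE * 1000   # seconds -> ms on disk
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a 4-D acquisition with mask and protocol
#'
#' Reads the 4-D data volume and 3-D binary mask, checks that the 4th
#' axis matches the protocol row count, and flattens the masked voxels
#' to an N x Ns signal matrix. Voxels are ordered in mask scan order
#' (first image axis fastest, R array order); the (i, j, k) coordinates
#' of each row are recorded so maps can be written back invertibly.
#'
#' @param dataPath 4-D NIfTI file.
#' @param maskPath 3-D NIfTI binary mask on the same spatial grid.
#' @param protocolPath protocol TSV (see [readProtocol()]).
#' @param normalize divide each voxel by the mean of its minimum-b,
#'   minimum-TE volumes (default TRUE, matching the model's unit-signal
#'   convention).
#' @return list with `image` (an [MRImageData-class]) and `header` (the
#'   RNifti image to template map output on).
#' @export
readImageData <- function(dataPath, maskPath, protocolPath, normalize = TRUE) {
  vol <- RNifti::readNifti(dataPath)
  msk <- RNifti::readNifti(maskPath)
  protocol <- readProtocol(protocolPath)
  dv <- dim(vol)
  if (length(dv) != 4L)
    stop(sprintf("expected a 4-D volume, got dimensions %s",
                 paste(dv, collapse = " x ")))
  if (dv[4] != nEncodings(protocol))
    stop(sprintf("4th axis length (%d) does not match protocol rows (%d)",
                 dv[4], nEncodings(protocol)))
  dm <- dim(msk)
  dm3 <- c(dm, 1L, 1L)[1:3]   # NIfTI readers may drop trailing singletons
  if (!identical(as.integer(dm3), as.integer(dv[1:3])))
    stop(sprintf("mask grid %s does not match volume grid %s",
                 paste(dm, collapse = " x "), paste(dv[1:3], collapse = " x ")))
  mv <- array(as.array(msk), dim = dm3)
  if (!all(mv %in% c(0, 1)))
    stop("mask must be binary (0/1)")
  idx <- which(mv == 1)
  if (!length(idx)) stop("empty mask")
  vox <- arrayInd(idx, dv[1:3])
  arr <- as.array(vol)
  sig <- matrix(arr[cbind(vox[rep(seq_len(nrow(vox)), dv[4]), ],
                          rep(seq_len(dv[4]), each = nrow(vox)))],
                nrow = nrow(vox), ncol = dv[4])
  if (anyNA(sig) || !all(is.finite(sig)))
    stop("masked voxels contain NaN/Inf values; clean or re-mask the data")
  norm <- rep(1, nrow(sig))
  if (normalize) {
    enc <- protocol@encodings
    sel <- rep(TRUE, nrow(enc))
    for (nm in colnames(enc)) sel <- sel & enc[, nm] == min(enc[, nm])
    norm <- rowMeans(sig[, sel, drop = FALSE])
    if (any(norm <= 0)) stop("non-positive reference signal in mask; cannot normalise")
    sig <- sig / norm
  }
  img <- imageData(sig, protocol, voxelIndex = vox,
                   imageDim = dv[1:3], normalization = norm)
  list(image = img, header = msk)
}

#' Write a voxel map back into image space
#'
#' @param values numeric length-N vector in the image's voxel order.
#' @param image the [MRImageData-class] the values belong to.
#' @param path output NIfTI path.
#' @param header optional RNifti image to copy geometry from.
#' @return the path, invisibly.
#' @export
writeMap <- function(values, image, path, header = NULL) {
  arr <- array(NA_real_, dim = image@imageDim)
  arr[image@voxelIndex] <- values
  img <- if (is.null(header)) RNifti::asNifti(arr)
         else RNifti::asNifti(arr, reference = header)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read sROIs from a JSON range file
#'
#' The file holds a list of sROIs, each a named object of
#' `[min, max]` ranges per spectral dimension, e.g.
#' `[{"ADC": [1e-4, 1e-3]}, {"ADC": [1e-3, 0.5], "T2star": [0.05, 0.3]}]`.
#'
#' @param path JSON file.
#' @param grid the [SpectralGrid-class] to rasterise the ranges on.
#' @return list of logical masks of length P.
#' @export
readSROIs <- function(path, grid) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(spec, function(r)
    sroiFromRanges(grid, lapply(r, function(v) as.numeric(unlist(v)))))
}

#' Write the standard output bundle of an InSpect fit
#'
#' Writes, into `outDir`: one float32 weight-map NIfTI per component
#' (`weights_F<m>.nii.gz`), the component spectra as CSV
#' (`components.csv`, columns = grid coordinates then one value column
#' per component, P rows) and as JSON, and a fit report JSON with the
#' log-likelihood trace, convergence info, configuration echo and
#' package version. The output directory is validated upfront.
#'
#' @param fit an [InspectFit-class].
#' @param image the fitted [MRImageData-class].
#' @param outDir output directory (created if missing).
#' @param header optional RNifti geometry template.
#' @param score optional [ModelScore-class] to include the BIC.
#' @param seed optional seed to echo in the report.
#' @return character vector of written paths, invisibly.
#' @export
writeFitOutputs <- function(fit, image, outDir, header = NULL, score = NULL,
                            seed = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2) != 0) stop(sprintf("cannot write to '%s'", outDir))
  M <- nComponents(fit)
  paths <- character(0)
  for (m in seq_len(M)) {
    p <- file.path(outDir, sprintf("weights_F%d.nii.gz", m))
    writeMap(fit@weights[, m], image, p, header = header)
    paths <- c(paths, p)
  }
  pts <- gridPoints(fit@components@grid)
  cs <- data.frame(pts, fit@components@values, check.names = FALSE)
  names(cs) <- c(colnames(pts), paste0("F", seq_len(M)))
  pcsv <- file.path(outDir, "components.csv")
  utils::write.csv(cs, pcsv, row.names = FALSE)
  pjson <- file.path(outDir, "components.json")
  jsonlite::write_json(list(grid = fit@components@grid@coords,
                            components = fit@components@values),
                       pjson, digits = NA)
  report <- list(
    version = as.character(utils::packageVersion("InSpect")),
    config = fit@config,
    seed = seed,
    iterations = fit@iterations,
    converged = fit@converged,
    logLik = fit@logLik,
    logLikTrace = fit@logLikTrace,
    maxWeightChangeTrace = fit@deltaTrace)
  if (!is.null(score))
    report$bic <- list(M = score@M, k = score@k, nObs = score@nObs,
                       bic = score@bic)
  prep <- file.path(outDir, "fit_report.json")
  jsonlite::write_json(report, prep, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, pcsv, pjson, prep))
}

#' Read a YAML run configuration
#'
#' Recognised keys: `grid.n_points`, `grid.ranges` (named list of
#' `[min, max]`), `kernel.name`, `weights.simplex`, `fit.M`, `fit.tol`,
#' `fit.max_iter`, `fit.alpha`, `fit.sigma`, `seed`. Missing keys get
#' the package defaults.
#'
#' @param path YAML file.
#' @return a list with a fully populated `grid` ([SpectralGrid-class])
#'   plus the scalar settings.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  gr <- cfg$grid
  ranges <- if (!is.null(gr$ranges))
    lapply(gr$ranges, as.numeric)
  else list(ADC = c(1e-4, 0.5), T2star = c(0.01, 0.3))
  nP <- if (!is.null(gr$n_points)) as.integer(gr$n_points) else 20L
  list(grid = makeDefaultGrid(nP, ranges),
       kernel = if (!is.null(cfg$kernel$name)) cfg$kernel$name
                else "separable-exponential",
       simplex = if (!is.null(cfg$weights$simplex)) isTRUE(cfg$weights$simplex)
                 else TRUE,
       M = cfg$fit$M, tol = cfg$fit$tol %||% 1e-3,
       maxIter = cfg$fit$max_iter %||% 5L,
       alpha = cfg$fit$alpha %||% 0.01,
       sigma = cfg$fit$sigma,
       seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
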