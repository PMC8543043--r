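## Kernel registry -----------------------------------------------------------
##
## A kernel family maps an encoding table (Ns x n_dims, named columns) and a
## grid-point table (P x n_dims, named columns) to the Ns x P kernel matrix.
## Only the separable exponential kernel is shipped:
##   K(t, omega) = exp(-TE / T2*) * exp(-b * ADC)
## and its single-dimension limits (multi-echo relaxometry exp(-TE/T2*),
## diffusion-only exp(-b*ADC)). New families can be registered by name.

.kernelRegistry <- new.env(parent = emptyenv())

#' Register a kernel family
#'
#' @param name registry key.
#' @param fun `function(encodings, points)` returning the Ns x P matrix;
#'   `encodings` is the protocol table, `points` the flattened grid-point
#'   table, both with named columns.
#' @export
registerKernel <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .kernelRegistry)
  invisible(name)
}

#' @rdname registerKernel
#' @export
listKernels <- function() ls(.kernelRegistry)

.getKernel <- function(name) {
  if (!exists(name, envir = .kernelRegistry))
    stop(sprintf("unknown kernel '%s'; available: %s", name,
                 paste(listKernels(), collapse = ", ")))
  get(name, envir = .kernelRegistry)
}

# decay exponent contributed by each (encoding dim, spectral dim) pairing
.sepExpPairs <- list(
  b  = list(spectral = "ADC",    rate = function(w) w),      # exp(-b * ADC)
  TE = list(spectral = "T2star", rate = function(w) 1 / w)   # exp(-TE / T2*)
)

.separableExponential <- function(encodings, points) {
  Ns <- nrow(encodings); P <- nrow(points)
  logK <- matrix(0, Ns, P)
  used <- character(0)
  for (enm in colnames(encodings)) {
    pair <- .sepExpPairs[[enm]]
    if (is.null(pair))
      stop(sprintf("separable-exponential kernel has no rule for encoding dimension '%s'", enm))
    if (!pair$spectral %in% colnames(points))
      stop(sprintf("encoding dimension '%s' needs spectral dimension '%s' on the grid",
                   enm, pair$spectral))
    logK <- logK - outer(encodings[, enm], pair$rate(points[, pair$spectral]))
    used <- c(used, pair$spectral)
  }
  unused <- setdiff(colnames(points), used)
  if (length(unused))
    stop(sprintf("grid dimension(s) %s have no matching encoding dimension",
                 paste(sQuote(unused), collapse = ", ")))
  exp(logK)
}

#' Evaluate the separable exponential kernel at one point
#'
#' Computes the unitless signal fraction
#' K(t, omega) = exp(-TE / T2*) * exp(-b * ADC) (terms present only for
#' the dimensions supplied, so a TE-only encoding with a T2*-only grid
#' point gives the multi-echo relaxometry kernel).
#'
#' @param t named numeric encoding vector (e.g. `c(b = 1000, TE = 0.078)`;
#'   b in s/mm^2, TE in seconds).
#' @param omega named numeric spectral coordinate vector (e.g.
#'   `c(ADC = 1e-3, T2star = 0.078)`; ADC in mm^2/s, T2* in seconds).
#' @return scalar in (0, 1] for b >= 0, TE >= 0.
#' @examples
#' evaluateKernel(c(b = 0, TE = 0), c(ADC = 0.01, T2star = 0.05))  # 1
#' evaluateKernel(c(b = 1000, TE = 0.078), c(ADC = 0.001, T2star = 0.078))
#' @export
evaluateKernel <- function(t, omega) {
  if (any(omega <= 0))
    stop("spectral coordinates must be strictly positive")
  if (!is.null(t["b"]) && !is.na(t["b"]) && t["b"] < 0)
    stop("b must be non-negative")
  enc <- matrix(t, nrow = 1, dimnames = list(NULL, names(t)))
  pts <- matrix(omega, nrow = 1, dimnames = list(NULL, names(omega)))
  as.numeric(.separableExponential(enc, pts))
}

#' Build the discretised kernel matrix K
#'
#' Evaluates the kernel at every (encoding, grid point) pair, so that a
#' voxel's noiseless signal is `S = K %*% F` for a flat spectrum F in
#' the grid's flattening order.
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @param grid a [SpectralGrid-class] whose dimensions match the
#'   protocol's encoding dimensions (b <-> ADC, TE <-> T2*).
#' @param kernel registry name of the kernel family.
#' @return a [KernelMatrix-class]
#' @export
buildKernel <- function(protocol, grid, kernel = "separable-exponential") {
  fun <- .getKernel(kernel)
  enc <- protocol@encodings
  pts <- gridPoints(grid)
  vals <- fun(enc, pts)
  if (!identical(dim(vals), c(nrow(enc), nrow(pts))))
    stop(sprintf("kernel '%s' returned a %s matrix; expected %d x %d",
                 kernel, paste(dim(vals), collapse = " x "),
                 nrow(enc), nrow(pts)))
  new("KernelMatrix", values = vals, protocol = protocol, grid = grid,
      kernelName = kernel)
}

#' Log-spaced default spectral grid
#'
#' Builds a grid with log-spaced coordinates in each dimension. The
#' defaults (20 x 20 points, ADC in \[1e-4, 0.5\] mm^2/s, T2* in
#' \[0.01, 0.3\] s) comfortably contain the spectral peaks observed in
#' placental diffusion-relaxometry data.
#'
#' @param nPoints integer, points per dimension (recycled); each >= 2.
#' @param ranges named list of `c(lower, upper)` ranges, lower > 0.
#' @return a [SpectralGrid-class]
#' @examples
#' makeDefaultGrid()                       # 20 x 20 T2*-ADC grid
#' makeDefaultGrid(3, list(ADC = c(1, 100)))
#' @export
makeDefaultGrid <- function(nPoints = 20L,
                            ranges = list(ADC = c(1e-4, 0.5),
                                          T2star = c(0.01, 0.3))) {
  nPoints <- rep_len(as.integer(nPoints), length(ranges))
  if (any(nPoints < 2L)) stop("need at least 2 points per dimension")
  co <- vector("list", length(ranges))
  names(co) <- names(ranges)
  for (i in seq_along(ranges)) {
    r <- ranges[[i]]
    if (length(r) != 2L || any(r <= 0) || r[2] <= r[1])
      stop(sprintf("range for '%s' must be positive with lower < upper",
                   names(ranges)[i]))
    co[[i]] <- exp(seq(log(r[1]), log(r[2]), length.out = nPoints[i]))
  }
  new("SpectralGrid", coords = co)
}

#' Spectral mode (peak location) of each component
#'
#' @param object a [SpectralComponents-class]
#' @return M x n_dims matrix of grid coordinates of each component's
#'   largest value (ties broken by lowest flat index).
#' @export
componentModes <- function(object) {
  pts <- gridPoints(object@grid)
  idx <- apply(object@values, 2, which.max)
  m <- pts[idx, , drop = FALSE]
  rownames(m) <- colnames(object@values)
  m
}
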