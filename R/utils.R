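## Internal numerical helpers.

# Non-negative least squares min ||A x - b||^2, x >= 0, by the
# Lawson-Hanson active-set method. Unlike off-the-shelf versions this
# returns the current feasible iterate (with its KKT violation already
# below a relaxed tolerance) instead of failing when near-collinear
# columns make the active set cycle slowly - the exponential kernels
# used here are severely ill-conditioned by construction.
.nnls <- function(A, b, itmax = NULL) {
  b <- as.numeric(b)
  n <- ncol(A)
  if (all(b == 0)) return(numeric(n))
  if (is.null(itmax)) itmax <- 10L * n + 50L
  tol <- 10 * .Machine$double.eps * norm(A, "2") * (max(dim(A)) + 1)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b)              # gradient of -0.5*objective at x = 0
  solvePassive <- function(p) {
    z <- numeric(n)
    z[p] <- tryCatch(qr.solve(A[, p, drop = FALSE], b),
                     error = function(e) {
                       Ap <- A[, p, drop = FALSE]
                       G <- crossprod(Ap)
                       diag(G) <- diag(G) * (1 + 1e-12) + 1e-300
                       as.numeric(solve(G, crossprod(Ap, b)))
                     })
    z
  }
  it <- 0L
  while (any(!passive) && any(w[!passive] > tol)) {
    free <- which(!passive)
    passive[free[which.max(w[free])]] <- TRUE
    z <- solvePassive(passive)
    while (any(z[passive] <= 0)) {
      it <- it + 1L
      if (it > itmax) return(x)     # feasible iterate, relaxed optimality
      q <- passive & (z <= 0)
      alpha <- min(x[q] / (x[q] - z[q]))
      x <- x + alpha * (z - x)
      passive <- passive & (abs(x) >= tol)
      z <- solvePassive(passive)
    }
    x <- z
    w <- crossprod(A, b - A %*% x)
    it <- it + 1L
    if (it > itmax) return(x)
  }
  x
}

# Simplex-constrained least squares: min ||A z - b||^2, z >= 0, sum z = 1.
.simplexLsq <- function(A, b) {
  M <- ncol(A)
  if (M == 1L) return(1)
  .simplexActiveSet(crossprod(A), as.numeric(crossprod(A, b)))
}

# Active-set solver for min z'Gz - 2c'z s.t. sum(z) = 1, z >= 0, with
# G = A'A SPD (or PSD). KKT stationarity on the passive (z > 0) set:
# 2(Gz - c)_j = mu for passive j, >= mu for active j, mu the multiplier
# of the equality constraint. M is small (number of components), so the
# dense KKT solves are negligible.
.simplexActiveSet <- function(G, c, maxit = NULL) {
  M <- length(c)
  if (M == 1L) return(1)
  if (is.null(maxit)) maxit <- 20L * M + 20L
  passive <- rep(TRUE, M)
  z <- rep(1 / M, M)
  ridge <- 1e-12 * max(diag(G), 1)
  for (iter in seq_len(maxit)) {
    p <- which(passive)
    k <- length(p)
    KKT <- rbind(cbind(2 * G[p, p, drop = FALSE], -1), c(rep(1, k), 0))
    rhs <- c(2 * c[p], 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      KKT[seq_len(k), seq_len(k)] <- KKT[seq_len(k), seq_len(k)] +
        diag(2 * ridge, k)
      sol <- solve(KKT, rhs)
    }
    zp <- sol[seq_len(k)]
    mu <- sol[k + 1]
    if (any(zp < -1e-10)) {
      passive[p[which.min(zp)]] <- FALSE
      if (sum(passive) == 0L) break
      next
    }
    z[] <- 0
    z[p] <- pmax(zp, 0)
    a <- which(!passive)
    if (!length(a)) return(z / sum(z))
    grad <- as.numeric(2 * (G %*% z - c))
    viol <- grad[a] - mu
    if (all(viol >= -1e-8 * max(1, abs(mu)))) return(z / sum(z))
    passive[a[which.min(viol)]] <- TRUE
  }
  # safeguarded fallback: clip and renormalise
  z <- pmax(z, 0)
  s <- sum(z)
  if (s > 0) z / s else rep(1 / M, M)
}

# Box-constrained least squares: min ||A z - b||^2, 0 <= z <= 1.
# Convex quadratic; L-BFGS-B with analytic gradient.
.boxLsq <- function(A, b, start = NULL) {
  M <- ncol(A)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  fn <- function(z) sum((A %*% z - b)^2)
  gr <- function(z) as.numeric(2 * (AtA %*% z - Atb))
  if (is.null(start)) start <- rep(0.5, M)
  res <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                      lower = rep(0, M), upper = rep(1, M),
                      control = list(maxit = 500, factr = 1e4))
  res$par
}

# Cholesky compression of a least-squares problem: for SPD Q = A^T A and
# c = A^T b, min ||R x - d||^2 with R = chol(Q), d = R^{-T} c has the
# same normal equations as the original problem. Returns R or NULL if
# Q is (numerically) not positive definite.
.cholCompress <- function(Q) {
  R <- tryCatch(chol(Q), error = function(e) NULL)
  R
}

.assertFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s must be finite", what))
  invisible(x)
}
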