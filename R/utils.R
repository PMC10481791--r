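# Shared numerical helpers. SI units throughout: meters, amperes, tesla, henry.

#' Magnetic permeability of vacuum (H/m)
#' @keywords internal
MU0 <- 4e-7 * pi

`%||%` <- function(a, b) if (is.null(a)) b else a

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z"), names(points))
    if (length(cols) == 3L) points <- points[, c("x", "y", "z")]
    points <- as.matrix(points)
  }
  if (is.numeric(points) && is.null(dim(points))) {
    if (length(points) != 3L)
      rlang::abort("`points` must be an n-by-3 matrix, a data frame with x/y/z columns, or a length-3 vector")
    points <- matrix(points, nrow = 1L)
  }
  points <- unname(as.matrix(points))
  if (ncol(points) != 3L || !is.numeric(points))
    rlang::abort("`points` must have three numeric columns (x, y, z in meters)")
  storage.mode(points) <- "double"
  points
}

row_norms <- function(m) sqrt(rowSums(m * m))

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Matrix-free GMRES (no restart, modified Gram-Schmidt Arnoldi)
#'
#' Solves `matvec(x) = b` to a relative residual tolerance. Used for the
#' second-kind surface-charge systems, which are well conditioned, so no
#' restarting or preconditioning is applied.
#'
#' @param matvec function taking and returning a numeric vector
#' @param b right-hand side
#' @param tol relative residual tolerance
#' @param max_iter maximum Krylov dimension
#' @param x0 optional initial guess (warm start)
#' @return list with `x`, `iterations`, `residuals` (relative residual history)
#' @keywords internal
gmres_solve <- function(matvec, b, tol = 1e-8, max_iter = 300L, x0 = NULL) {
  n <- length(b)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(x = numeric(n), iterations = 0L, residuals = numeric(0), converged = TRUE))
  }
  x0 <- x0 %||% numeric(n)
  r0 <- b - matvec(x0)
  beta <- sqrt(sum(r0^2))
  if (beta / bnorm <= tol) {
    return(list(x = x0, iterations = 0L, residuals = beta / bnorm, converged = TRUE))
  }
  m <- min(max_iter, n)
  V <- matrix(0, n, m + 1L)
  Hh <- matrix(0, m + 1L, m)
  cs <- numeric(m); sn <- numeric(m)
  g <- numeric(m + 1L); g[1] <- beta
  V[, 1] <- r0 / beta
  res_hist <- numeric(0)
  k_used <- 0L
  for (k in seq_len(m)) {
    w <- matvec(V[, k])
    for (i in seq_len(k)) {
      Hh[i, k] <- sum(w * V[, i])
      w <- w - Hh[i, k] * V[, i]
    }
    Hh[k + 1L, k] <- sqrt(sum(w^2))
    if (Hh[k + 1L, k] > 0) V[, k + 1L] <- w / Hh[k + 1L, k]
    # apply stored Givens rotations, then form a new one
    for (i in seq_len(k - 1L)) {
      t1 <- cs[i] * Hh[i, k] + sn[i] * Hh[i + 1L, k]
      Hh[i + 1L, k] <- -sn[i] * Hh[i, k] + cs[i] * Hh[i + 1L, k]
      Hh[i, k] <- t1
    }
    d <- sqrt(Hh[k, k]^2 + Hh[k + 1L, k]^2)
    cs[k] <- Hh[k, k] / d
    sn[k] <- Hh[k + 1L, k] / d
    Hh[k, k] <- d
    Hh[k + 1L, k] <- 0
    g[k + 1L] <- -sn[k] * g[k]
    g[k] <- cs[k] * g[k]
    res <- abs(g[k + 1L]) / bnorm
    res_hist <- c(res_hist, res)
    k_used <- k
    if (res <= tol) break
  }
  y <- backsolve(Hh[seq_len(k_used), seq_len(k_used), drop = FALSE], g[seq_len(k_used)])
  x <- x0 + V[, seq_len(k_used), drop = FALSE] %*% y
  list(x = as.numeric(x), iterations = k_used, residuals = res_hist,
       converged = res_hist[length(res_hist)] <= tol)
}
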