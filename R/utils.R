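# Internal numerical helpers shared across modules.

#' Trapezoidal integral
#'
#' @param x strictly increasing abscissae.
#' @param y values of the integrand at `x`.
#' @return scalar integral estimate.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Adaptive quadrature wrapper. Splits at `split` (typically the mode of the
# weight) so stats::integrate sees monotone tails; tolerances per the package
# defaults (abs 1e-12, rel 1e-10).
quad <- function(f, lower, upper, split = NULL, rel.tol = 1e-10,
                 abs.tol = 1e-12, subdivisions = 400L) {
  one <- function(a, b) {
    stats::integrate(f, a, b, rel.tol = rel.tol, abs.tol = abs.tol,
                     subdivisions = subdivisions, stop.on.error = FALSE)$value
  }
  if (!is.null(split) && is.finite(split) && split > lower && split < upper) {
    one(lower, split) + one(split, upper)
  } else {
    one(lower, upper)
  }
}

# Solve S y = b for symmetric positive definite S via Cholesky, falling back
# to a symmetric eigendecomposition; errors when S is not positive definite,
# reporting the smallest eigenvalue.
sym_solve <- function(S, b, label = "C") {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) {
    return(backsolve(ch, forwardsolve(t(ch), b)))
  }
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    stop(sprintf(
      "matrix %s is not positive definite (smallest eigenvalue %.3e)",
      label, min(ev$values)), call. = FALSE)
  }
  ev$vectors %*% ((crossprod(ev$vectors, b)) / ev$values)
}

# Directed and symmetric Hausdorff distance between two polylines given as
# point matrices (rows = points).
hausdorff_distance <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  d2 <- function(A, B) {
    # for each row of A, distance to nearest row of B
    vapply(seq_len(nrow(A)), function(i) {
      sqrt(min(colSums((t(B) - A[i, ])^2)))
    }, numeric(1))
  }
  max(max(d2(P, Q)), max(d2(Q, P)))
}

# Linear interpolation of a density onto a new grid; values outside the
# original support become 0.
interp_density <- function(grid, values, new_grid) {
  stats::approx(grid, values, xout = new_grid, yleft = 0, yright = 0,
                ties = "ordered")$y
}
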