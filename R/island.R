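# Stochastic logistic island model with immigration:
#   dn = [n(r - lambda n) + m] dt + sqrt(n) dxi,   n in (0, Inf)
# stationary density u(n) ~ n^(2m-1) exp(-lambda n^2 + 2 r n), valid as a
# maximum-entropy ansatz only for m > 1/2 (otherwise <1/n> diverges).

# exponent of the unnormalized moment integrand n^(k+2m-1) (log n)^j w(n)
island_log_weight <- function(n, k, forces) {
  f <- unname(unlist(forces))
  (k + 2 * f[3] - 1) * log(n) - f[2] * n^2 + 2 * f[1] * n
}

# interior maximum of the k-weighted integrand (exists iff k + 2m - 1 > 0)
island_weight_mode <- function(k, forces) {
  f <- unname(unlist(forces))
  p <- k + 2 * f[3] - 1
  if (p <= 0) return(NA_real_)
  (f[1] + sqrt(f[1]^2 + 2 * f[2] * p)) / (2 * f[2])
}

# log of the unnormalized moment integral, with (log n)^j weight:
#   log | integral_0^Inf n^(k+2m-1) (log n)^j exp(-lambda n^2 + 2 r n) dn |
# All work happens in log space (shift by the integrand maximum), so large
# r^2/lambda never overflows. For j > 0 the integrand changes sign at n = 1,
# so the integral is split there as well as at the mode.
island_moment_integral <- function(k, j, forces, rel.tol = 1e-10) {
  f <- unname(unlist(forces))
  if (k + 2 * f[3] <= 0) {
    stop(sprintf(
      "moment integral G(%g) diverges: requires k + 2m > 0 (here k + 2m = %g)",
      k, k + 2 * f[3]), call. = FALSE)
  }
  if (f[2] <= 0) stop("lambda must be > 0 (non-integrable tail)",
                      call. = FALSE)
  mode <- island_weight_mode(k, forces)
  ref <- if (is.na(mode)) max(1, f[1] / f[2]) else mode
  M <- island_log_weight(ref, k, forces)
  g <- function(n) exp(island_log_weight(n, k, forces) - M) *
    (if (j > 0) log(n)^j else 1)
  pts <- sort(unique(c(0, if (j > 0) 1, if (!is.na(mode)) mode, Inf)))
  I <- 0
  for (i in seq_len(length(pts) - 1)) {
    I <- I + stats::integrate(g, pts[i], pts[i + 1], rel.tol = rel.tol,
                              abs.tol = 1e-14, subdivisions = 500L,
                              stop.on.error = FALSE)$value
  }
  list(log_scale = M, value = I)   # integral = exp(M) * value
}

#' Unnormalized island moment integrals G(k)
#'
#' \eqn{G(k) = \int_0^\infty n^{k+2m-1} e^{-\lambda n^2 + 2 r n}\,dn},
#' finite iff \eqn{k + 2m > 0}. \eqn{G(0) = Z} is the partition function and
#' normalized moments are ratios: \eqn{\langle n^k\rangle = G(k)/G(0)}.
#'
#' Two routes are implemented. `"quadrature"` (production) evaluates the
#' integral adaptively in log space. `"kummer"` evaluates the closed form
#' \deqn{G(k) = \tfrac12\Big[\lambda^{-\nu/2}\,\Gamma(\tfrac\nu2)\,
#'   {}_1F_1(\tfrac\nu2;\tfrac12;z) + 2r\,\lambda^{-(\nu+1)/2}\,
#'   \Gamma(\tfrac{\nu+1}2)\,{}_1F_1(\tfrac{\nu+1}2;\tfrac32;z)\Big]}
#' with \eqn{\nu = k+2m}, \eqn{z = r^2/\lambda}, used as an independent
#' cross-check of the quadrature (for \eqn{z \ge 0} the confluent
#' hypergeometric series has all-positive terms, so double precision keeps
#' ~1e-13 relative accuracy).
#'
#' @param k real moment order (can be negative; `k = -1` gives the
#'   \eqn{\langle 1/n\rangle} integral, divergent at \eqn{m \le 1/2}).
#' @param forces island forces `c(r, lambda, m)` with `lambda > 0`.
#' @param method `"quadrature"` (default) or `"kummer"`.
#' @return scalar value of the integral.
#' @seealso [island_logG()] for the overflow-safe logarithm, [island_H()]
#'   for the \eqn{(\log n)^j}-weighted integrals.
#' @export
island_G <- function(k, forces, method = c("quadrature", "kummer")) {
  method <- match.arg(method)
  if (method == "kummer") return(island_G_kummer(k, forces))
  I <- island_moment_integral(k, 0, forces)
  exp(I$log_scale) * I$value
}

#' @rdname island_G
#' @export
island_logG <- function(k, forces) {
  I <- island_moment_integral(k, 0, forces)
  I$log_scale + log(I$value)
}

island_G_kummer <- function(k, forces) {
  f <- unname(unlist(forces))
  nu <- k + 2 * f[3]
  if (nu <= 0) {
    stop(sprintf(
      "moment integral G(%g) diverges: requires k + 2m > 0 (here k + 2m = %g)",
      k, nu), call. = FALSE)
  }
  if (f[2] <= 0) stop("lambda must be > 0 (non-integrable tail)",
                      call. = FALSE)
  z <- f[1]^2 / f[2]
  t1 <- exp(lgamma(nu / 2) - (nu / 2) * log(f[2])) *
    kummer_1f1(nu / 2, 1 / 2, z)
  t2 <- 2 * f[1] * exp(lgamma((nu + 1) / 2) - ((nu + 1) / 2) * log(f[2])) *
    kummer_1f1((nu + 1) / 2, 3 / 2, z)
  (t1 + t2) / 2
}

#' Confluent hypergeometric function (Kummer's M)
#'
#' Power series for \eqn{{}_1F_1(a; b; z)}. For \eqn{z < 0} the Kummer
#' transformation \eqn{{}_1F_1(a;b;z) = e^z {}_1F_1(b-a;b;-z)} is applied so
#' the summed series always has nonnegative argument (and, for the
#' parameters arising in the island moment calculus, all-positive terms —
#' no cancellation).
#'
#' @param a,b parameters (`b` not a nonpositive integer).
#' @param z argument.
#' @return scalar value of the series.
#' @export
kummer_1f1 <- function(a, b, z) {
  if (b <= 0 && b == round(b)) stop("b must not be a nonpositive integer",
                                    call. = FALSE)
  if (z < 0) return(exp(z) * kummer_1f1(b - a, b, -z))
  term <- 1; s <- 1
  for (j in 0:10000) {
    term <- term * (a + j) / (b + j) * z / (j + 1)
    s <- s + term
    if (abs(term) < 1e-17 * abs(s) && j > z) return(s)
  }
  stop("1F1 series did not converge", call. = FALSE)
}

#' Log-weighted island moment integrals H(k, j)
#'
#' \eqn{H(k,j) = \int_0^\infty n^{k+2m-1} (\log n)^j
#' e^{-\lambda n^2 + 2 r n}\,dn}, so that \eqn{H(k,0) = G(k)} and
#' \eqn{\langle n^k (\log n)^j \rangle = H(k,j)/G(0)}. Formally
#' \eqn{H(k,j) = 2^{-j}\,\partial^j G(k)/\partial m^j}; the production route
#' is direct log-weight quadrature, with the central finite difference of
#' `G` in `m` (`method = "fd"`) kept as a numerically independent
#' cross-check.
#'
#' @inheritParams island_G
#' @param j nonnegative integer power of `log(n)` (j <= 2).
#' @param method `"quadrature"` (default) or `"fd"`.
#' @return scalar value of the integral.
#' @export
island_H <- function(k, j, forces, method = c("quadrature", "fd")) {
  method <- match.arg(method)
  stopifnot(j >= 0, j <= 2, j == round(j))
  if (j == 0 && method == "quadrature") return(island_G(k, forces))
  if (method == "fd") {
    f <- unname(unlist(forces))
    # small relative step: G grows like exp(2 <log n> m), so the truncation
    # error scales as (2 h <log n>)^2/6
    h <- 5e-5 * max(1, abs(f[3]))
    shift <- function(dm) { g <- f; g[3] <- f[3] + dm; g }
    if (j == 0) return(island_G(k, f))
    if (j == 1) {
      return((island_G(k, shift(h)) - island_G(k, shift(-h))) / (2 * h) / 2)
    }
    return((island_G(k, shift(h)) - 2 * island_G(k, f) +
              island_G(k, shift(-h))) / h^2 / 4)
  }
  I <- island_moment_integral(k, j, forces)
  exp(I$log_scale) * I$value
}

#' Normalized stationary moments of the island model
#'
#' Computes, under the stationary density at `forces`, every moment entering
#' the island DME matrices: \eqn{\langle n^k\rangle} for
#' \eqn{k \in \{-1,1,2,3,4\}}, \eqn{\langle\log n\rangle},
#' \eqn{\langle n\log n\rangle}, \eqn{\langle n^2\log n\rangle} and
#' \eqn{\langle(\log n)^2\rangle}, sharing a single normalization
#' \eqn{\log G(0)}.
#'
#' @param forces island forces `c(r, lambda, m)`, DME-valid (`m > 1/2`).
#' @return named list of moments plus `logZ`.
#' @export
island_moments <- function(forces) {
  assert_valid_forces(island_model(), forces)
  logG0 <- island_logG(0, forces)
  mk <- function(k) exp(island_logG(k, forces) - logG0)
  lw <- function(k, j) {
    I <- island_moment_integral(k, j, forces)
    exp(I$log_scale - logG0) * I$value
  }
  list(n = mk(1), n2 = mk(2), n3 = mk(3), n4 = mk(4), ninv = mk(-1),
       logn = lw(0, 1), nlogn = lw(1, 1), n2logn = lw(2, 1),
       logn2 = lw(0, 2), logZ = logG0)
}

#' Island DME matrices
#'
#' Assembles the moment matrices of the island model at an effective force
#' point from the hypergeometric moment calculus:
#' \deqn{B = \frac{1}{G(0)}\begin{pmatrix} G(1) & -G(2) & G(0)\\
#'  -G(2) & G(3) & -G(1)\\ G(0) & -G(1) & G(-1)\end{pmatrix},\qquad
#'  V = \big(0,\ -\langle n\rangle/2,\ -\langle 1/n\rangle/2\big),}
#' and the covariance matrix of the observables
#' \eqn{A = (n, -n^2/2, \log n)}. The sensitivity matrix defaults to the
#' chain-rule-consistent \eqn{C = 2\,\mathrm{Cov}} (the stationary exponent
#' is \eqn{2\alpha\cdot A}, so \eqn{\partial\langle A\rangle/\partial\alpha
#' = 2\,\mathrm{Cov}}); `scaling = "plain"` exposes the unscaled covariance
#' variant for comparison.
#'
#' @param forces island forces `c(r, lambda, m)`, DME-valid (`m > 1/2`).
#' @param scaling `"chain"` (default, `C = 2 Cov`) or `"plain"`
#'   (`C = Cov`).
#' @return list with `B`, `V`, `Cov`, `C`, `A`, `moments`.
#' @export
island_matrices <- function(forces, scaling = c("chain", "plain")) {
  scaling <- match.arg(scaling)
  v <- check_dme_validity(forces)
  if (!v$valid) {
    stop(paste(v$violations, collapse = "; "), call. = FALSE)
  }
  mo <- island_moments(forces)
  B <- matrix(c(mo$n,  -mo$n2,  1,
                -mo$n2, mo$n3, -mo$n,
                1,     -mo$n,   mo$ninv), 3, 3)
  V <- c(0, -mo$n / 2, -mo$ninv / 2)
  Cov <- matrix(0, 3, 3)
  Cov[1, 1] <- mo$n2 - mo$n^2
  Cov[1, 2] <- Cov[2, 1] <- -(mo$n3 - mo$n * mo$n2) / 2
  Cov[1, 3] <- Cov[3, 1] <- mo$nlogn - mo$n * mo$logn
  Cov[2, 2] <- (mo$n4 - mo$n2^2) / 4
  Cov[2, 3] <- Cov[3, 2] <- -(mo$n2logn - mo$n2 * mo$logn) / 2
  Cov[3, 3] <- mo$logn2 - mo$logn^2
  C <- if (scaling == "chain") 2 * Cov else Cov
  list(B = B, V = V, Cov = Cov, C = C,
       A = c(n = mo$n, mn2h = -mo$n2 / 2, logn = mo$logn), moments = mo)
}

#' Raw observable dynamics of the island model
#'
#' Evaluates the (unclosed) moment equations
#' \deqn{d\langle n\rangle/dt = r\langle n\rangle - \lambda\langle n^2\rangle
#'   + m,}
#' \deqn{d(-\langle n^2\rangle/2)/dt = -(m + 1/2)\langle n\rangle
#'   - r\langle n^2\rangle + \lambda\langle n^3\rangle,}
#' \deqn{d\langle\log n\rangle/dt = r - \lambda\langle n\rangle
#'   + (m - 1/2)\langle 1/n\rangle,}
#' at a given set of moments and applied forces. At the stationary moments
#' of the applied forces the result vanishes (quasi-stationarity identity
#' \eqn{B\alpha + V = 0}).
#'
#' @param moments list with (at least) `n`, `n2`, `n3`, `ninv`, e.g. from
#'   [island_moments()].
#' @param applied island force vector `c(r, lambda, m)`.
#' @return numeric 3-vector, the time derivative of
#'   \eqn{(\langle n\rangle, -\langle n^2\rangle/2, \langle\log n\rangle)}.
#' @export
island_moment_rhs <- function(moments, applied) {
  need <- c("n", "n2", "n3", "ninv")
  miss <- setdiff(need, names(moments))
  if (length(miss)) {
    stop("missing moments: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  f <- unname(unlist(applied))
  mo <- lapply(moments, unname)
  c(f[1] * mo$n - f[2] * mo$n2 + f[3],
    -(f[3] + 1 / 2) * mo$n - f[1] * mo$n2 + f[2] * mo$n3,
    f[1] - f[2] * mo$n + (f[3] - 1 / 2) * mo$ninv)
}

#' Check DME validity of island forces
#'
#' The maximum-entropy ansatz behaves as \eqn{n^{2m-1}} near \eqn{n = 0};
#' for \eqn{m \le 1/2} the expectation \eqn{\langle 1/n\rangle} entering the
#' matrix \eqn{B} is unbounded (log-divergent exactly at the \eqn{m = 1/2}
#' boundary) and the reduction is refused.
#'
#' @param forces island force vector `c(r, lambda, m)`.
#' @return list with `valid` (logical), `violations` (character vector) and
#'   `diverging` (names of the diverging quantities, if any).
#' @export
check_dme_validity <- function(forces) {
  f <- unlist(forces)
  violations <- character(0); diverging <- character(0)
  if (!all(is.finite(f))) violations <- c(violations, "non-finite force entry")
  if (is.finite(f[2]) && f[2] <= 0) {
    violations <- c(violations, "lambda must be > 0 (non-integrable tail)")
  }
  if (is.finite(f[3]) && f[3] <= 0.5) {
    violations <- c(violations, sprintf(
      paste0("m = %g <= 1/2: the stationary ansatz ~ n^(2m-1) makes <1/n> ",
             "in the matrix B %s; the boundary-layer treatment needed for ",
             "weak migration is out of scope"),
      f[3], if (f[3] == 0.5) "log-divergent at the boundary" else "divergent"))
    diverging <- c(diverging, "<1/n>")
  }
  list(valid = length(violations) == 0, violations = violations,
       diverging = diverging)
}

#' Locate the migration validity frontier numerically
#'
#' Probes integrability of \eqn{\langle 1/n\rangle} without using the known
#' threshold: for a trial `m` it integrates the \eqn{\langle 1/n\rangle}
#' integrand over the shrinking windows \eqn{(10^{-5}, 10^{-3})} and
#' \eqn{(10^{-7}, 10^{-5})} and declares convergence when the increment
#' ratio falls below \eqn{1 - 0.005} (for a local power law
#' \eqn{n^{2m-2}} the ratio is \eqn{10^{-4(m - 1/2)}}: below 1 only for
#' \eqn{m > 1/2}). Bisection on this probe localizes the DME validity
#' frontier; the probe threshold biases the estimate upward by about
#' \eqn{5\times10^{-4}}.
#'
#' @param r,lambda island forces held fixed during the probe.
#' @param lo,hi initial bisection bracket for `m`.
#' @param tol bracket width at which bisection stops.
#' @return the estimated frontier migration rate.
#' @export
island_validity_frontier <- function(r = 0.1, lambda = 0.002,
                                     lo = 0.2, hi = 1, tol = 1e-4) {
  probe <- function(m) {
    f <- function(n) exp((2 * m - 2) * log(n) - lambda * n^2 + 2 * r * n)
    d1 <- quad(f, 1e-5, 1e-3)
    d2 <- quad(f, 1e-7, 1e-5)
    d2 / d1 < 1 - 0.005      # TRUE: increments shrink => integrable
  }
  if (probe(lo) || !probe(hi)) stop("bracket does not straddle the frontier",
                                    call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (probe(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
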