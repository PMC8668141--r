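#' Exact Gaussian moments of the Ornstein-Uhlenbeck process
#'
#' For the SDE \eqn{dx = \beta(t)(\mu(t)-x)\,dt + \sigma_0\,d\xi} started
#' from its stationary Gaussian at \eqn{(\mu_0,\beta_0)}, the solution stays
#' Gaussian with mean and variance obeying
#' \eqn{\dot m = \beta(\mu - m)}, \eqn{\dot v = \sigma_0^2 - 2\beta v}.
#' For constant coefficients the closed form is
#' \deqn{m(t) = \mu_\infty + (\mu_0-\mu_\infty)e^{-\beta_\infty t},\quad
#'  v(t) = \frac{\sigma_0^2}{2\beta_0}e^{-2\beta_\infty t} +
#'         \frac{\sigma_0^2}{2\beta_\infty}(1 - e^{-2\beta_\infty t}).}
#' The ODE route integrates the same system for arbitrary protocols (it is
#' the \eqn{(m, v)} form of the f/g/h Gaussian-shape system, with
#' \eqn{h = m}, \eqn{g = 1/(2v)} and \eqn{f} fixed by normalization).
#'
#' @param mu0,beta0 initial stationary parameters (variance
#'   \eqn{\sigma_0^2/(2\beta_0)}).
#' @param sigma0 constant noise magnitude.
#' @param protocol a [drive_protocol] for the applied \eqn{(\mu, \beta)}.
#' @param times increasing output times starting at 0.
#' @param method `"auto"` uses the closed form when the protocol is constant
#'   on \eqn{t > 0} and the ODE route otherwise.
#' @return data.frame with columns `t`, `m`, `v`.
#' @export
ou_exact_moments <- function(mu0, beta0, sigma0, protocol, times,
                             method = c("auto", "closed", "ode")) {
  method <- match.arg(method)
  stopifnot(beta0 > 0, sigma0 > 0, !is.unsorted(times, strictly = TRUE))
  v0 <- sigma0^2 / (2 * beta0)
  constant_after_0 <- length(protocol$switch_times(
    min(1e-12, min(times[times > 0], Inf)), max(times))) == 0
  if (method == "closed" || (method == "auto" && constant_after_0)) {
    f1 <- protocol$evaluate(max(times))
    mu_inf <- f1[[1]]; beta_inf <- f1[[2]]
    if (beta_inf <= 0) stop("beta must stay positive", call. = FALSE)
    m <- mu_inf + (mu0 - mu_inf) * exp(-beta_inf * times)
    v <- v0 * exp(-2 * beta_inf * times) +
      sigma0^2 / (2 * beta_inf) * (1 - exp(-2 * beta_inf * times))
    return(data.frame(t = times, m = m, v = v))
  }
  deriv <- function(t, y, parms) {
    f <- protocol$evaluate(t)
    if (f[[2]] <= 0) stop("beta must stay positive", call. = FALSE)
    list(c(f[[2]] * (f[[1]] - y[1]), sigma0^2 - 2 * f[[2]] * y[2]))
  }
  t0 <- times[1]
  bounds <- sort(unique(c(t0, protocol$switch_times(t0, max(times)),
                          max(times))))
  y <- c(m = mu0, v = v0)
  out <- matrix(NA_real_, length(times), 2)
  out[1, ] <- y
  for (k in seq_len(length(bounds) - 1)) {
    idx <- which(times > bounds[k] & times <= bounds[k + 1])
    seg <- sort(unique(c(bounds[k], times[idx], bounds[k + 1])))
    sol <- deSolve::lsoda(y, seg, deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    if (length(idx)) out[idx, ] <- sol[match(times[idx], sol[, 1]), -1]
    y <- sol[nrow(sol), -1]
  }
  data.frame(t = times, m = out[, 1], v = out[, 2])
}

#' OU moment matrices in closed form
#'
#' At effective forces \eqn{(\mu^\ast, \beta^\ast)} the stationary density
#' is Gaussian with mean \eqn{\mu^\ast} and variance
#' \eqn{v = \sigma_0^2/(2\beta^\ast)}, and the matrices of
#' [moment_matrices()] have closed Gaussian-moment forms:
#' \deqn{B = \begin{pmatrix} 1/2 & \mu^\ast \\ \mu^\ast &
#'   2\mu^{\ast 2} + \sigma_0^2/\beta^\ast \end{pmatrix},\qquad
#'  C = \frac{1}{2\beta^\ast}\begin{pmatrix} 1 & 2\mu^\ast \\ 2\mu^\ast &
#'   \sigma_0^2/\beta^\ast + 4\mu^{\ast 2} \end{pmatrix},}
#' with \eqn{C = \mathrm{Cov}(A)/\sigma_0^2} the scaled covariance of
#' \eqn{A = (x, x^2)} and \eqn{V = (0, \sigma_0^2)}.
#'
#' @param mu_star,beta_star effective forces; `beta_star > 0`.
#' @param sigma0 noise magnitude.
#' @return list with `B`, `V`, `Cov`, `C`, `Cinv`, `A` (see
#'   [moment_matrices()]; `Cinv` is the closed-form inverse
#'   \eqn{C^{-1} = \frac{2\beta^\ast}{\sigma_0^2}
#'   \begin{pmatrix} 4\beta^\ast\mu^{\ast2}+\sigma_0^2 & -2\mu^\ast\beta^\ast\\
#'   -2\mu^\ast\beta^\ast & \beta^\ast\end{pmatrix}}).
#' @export
ou_matrices <- function(mu_star, beta_star, sigma0) {
  if (beta_star <= 0) stop("beta* must be > 0", call. = FALSE)
  v <- sigma0^2 / (2 * beta_star)
  B <- matrix(c(1 / 2, mu_star,
                mu_star, 2 * mu_star^2 + sigma0^2 / beta_star), 2, 2)
  C <- (1 / (2 * beta_star)) *
    matrix(c(1, 2 * mu_star,
             2 * mu_star, sigma0^2 / beta_star + 4 * mu_star^2), 2, 2)
  Cinv <- (2 * beta_star / sigma0^2) *
    matrix(c(4 * beta_star * mu_star^2 + sigma0^2, -2 * mu_star * beta_star,
             -2 * mu_star * beta_star, beta_star), 2, 2)
  list(B = B, V = c(0, sigma0^2), Cov = sigma0^2 * C, C = C, Cinv = Cinv,
       A = c(x = mu_star, x2 = mu_star^2 + v))
}

#' Decoupled OU effective-force dynamics
#'
#' The reduced dynamics of the OU effective forces decouple into
#' \deqn{d\mu^\ast/dt = \beta(t)\,(\mu(t) - \mu^\ast),\qquad
#'       d\beta^\ast/dt = 2\beta^\ast(\beta(t) - \beta^\ast),}
#' a linear equation for \eqn{\mu^\ast} and a logistic one for
#' \eqn{\beta^\ast}; both are independent of the noise magnitude
#' \eqn{\sigma_0}.
#'
#' @param mu_star,beta_star current effective forces (`beta_star > 0`).
#' @param mu,beta instantaneous applied forces.
#' @return numeric vector `c(dmu_star, dbeta_star)`.
#' @export
ou_dme_rhs <- function(mu_star, beta_star, mu, beta) {
  if (beta_star <= 0) stop("beta* must be > 0", call. = FALSE)
  c(mu = beta * (mu - mu_star), beta = 2 * beta_star * (beta - beta_star))
}

#' DME solution of the OU process
#'
#' Integrates the decoupled effective-force system from
#' \eqn{(\mu_0, \beta_0)} under an arbitrary drive protocol and maps the
#' effective forces to the Gaussian state via \eqn{m = \mu^\ast},
#' \eqn{v = \sigma_0^2/(2\beta^\ast)}. For the OU process this reduction is
#' exact: for any protocol the result coincides with [ou_exact_moments()]
#' up to integration tolerance, and the \eqn{(\mu^\ast,\beta^\ast)} path
#' itself does not depend on \eqn{\sigma_0}.
#'
#' @inheritParams ou_exact_moments
#' @param rtol,atol integration tolerances.
#' @return data.frame with columns `t`, `mu_star`, `beta_star`, `m`, `v`.
#' @export
ou_dme_solution <- function(mu0, beta0, sigma0, protocol, times,
                            rtol = 1e-8, atol = 1e-10) {
  model <- ou_model(sigma0)
  path <- integrate_effective_forces(
    model, protocol, c(mu = mu0, beta = beta0), times,
    rtol = rtol, atol = atol,
    rhs_fn = function(eff, applied)
      ou_dme_rhs(eff[[1]], eff[[2]], applied[[1]], applied[[2]]))
  data.frame(t = times,
             mu_star = path$forces[, 1], beta_star = path$forces[, 2],
             m = path$forces[, 1],
             v = sigma0^2 / (2 * path$forces[, 2]))
}
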