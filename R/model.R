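#' Model specification for the dynamic maximum entropy engine
#'
#' A `dme_model` bundles everything the generic engine needs to know about a
#' one-dimensional diffusion whose stationary density has the
#' exponential-family ("potential") form
#' \deqn{\bar u_\alpha(x) \propto \nu(x)\, \exp[s\, \alpha_c \cdot A(x)],}
#' where \eqn{\nu = 1/g^2} is the no-force baseline, \eqn{A} the vector of
#' observables, \eqn{s} a constant force scale and \eqn{\alpha_c} the
#' canonical (exponent) force coordinates. The corresponding SDE is
#' \eqn{dx = (g^2 s/2)\,\partial_x[\alpha_c \cdot A]\,dt + g\,d\xi}.
#'
#' Two models ship with the package: [ou_model()] (Ornstein-Uhlenbeck,
#' natural forces \eqn{(\mu,\beta)}, canonical \eqn{(2\mu\beta,-\beta)},
#' scale \eqn{s = 1/\sigma_0^2}) and [island_model()] (stochastic logistic
#' growth with immigration, natural = canonical forces \eqn{(r,\lambda,m)},
#' scale \eqn{s = 2}).
#'
#' @section Fields:
#' \describe{
#'   \item{name, dim, force_names}{identifier, number of forces d, names of
#'     the natural parameters.}
#'   \item{domain}{open interval of the state variable.}
#'   \item{s}{constant force scale multiplying \eqn{\alpha_c \cdot A} in the
#'     stationary exponent.}
#'   \item{observables, observables_grad, observables_lap}{vectorized maps
#'     x -> matrix (length(x) by d) of \eqn{A}, \eqn{A'}, \eqn{A''}.}
#'   \item{noise_g2, noise_g2_prime}{squared noise amplitude \eqn{g^2(x)}
#'     and its derivative.}
#'   \item{log_baseline}{\eqn{\log \nu(x)}.}
#'   \item{to_canonical, from_canonical, canonical_jacobian}{bijection
#'     between natural forces and \eqn{\alpha_c}, with Jacobian
#'     \eqn{\partial\alpha_c/\partial(\mathrm{natural})}.}
#'   \item{validate}{returns a character vector of violated constraints
#'     (empty when the force vector is admissible for the DME ansatz).}
#'   \item{matrices}{optional closed-form/semianalytic route to the moment
#'     matrices, same contract as [moment_matrices()].}
#'   \item{default_grid}{builds a state grid wide enough that the boundary
#'     density is negligible for a given (list of) force vector(s).}
#' }
#'
#' @param sigma0 constant noise magnitude of the OU process (> 0).
#' @return an object of class `dme_model`.
#' @name dme_model
NULL

new_dme_model <- function(fields) structure(fields, class = "dme_model")

#' @export
print.dme_model <- function(x, ...) {
  cat(sprintf("<dme_model '%s'> d = %d, forces (%s), domain (%g, %g)\n",
              x$name, x$dim, paste(x$force_names, collapse = ", "),
              x$domain[1], x$domain[2]))
  invisible(x)
}

#' Validate a force vector, erroring on violations
#' @param model a [dme_model].
#' @param forces named numeric vector of natural forces.
#' @keywords internal
assert_valid_forces <- function(model, forces) {
  bad <- model$validate(forces)
  if (length(bad)) {
    stop(sprintf("invalid %s forces (%s): %s", model$name,
                 paste(sprintf("%s=%g", model$force_names, forces),
                       collapse = ", "),
                 paste(bad, collapse = "; ")), call. = FALSE)
  }
  invisible(forces)
}

#' @rdname dme_model
#' @export
ou_model <- function(sigma0 = 0.1) {
  stopifnot(sigma0 > 0)
  m <- new_dme_model(list(
    name = "ou", dim = 2L, force_names = c("mu", "beta"),
    domain = c(-Inf, Inf),
    s = 1 / sigma0^2, sigma0 = sigma0,
    observables = function(x) cbind(x = x, x2 = x^2),
    observables_grad = function(x) cbind(rep(1, length(x)), 2 * x),
    observables_lap = function(x) cbind(rep(0, length(x)), rep(2, length(x))),
    noise_g2 = function(x) rep(sigma0^2, length(x)),
    noise_g2_prime = function(x) rep(0, length(x)),
    log_baseline = function(x) rep(-2 * log(sigma0), length(x)),
    to_canonical = function(f) c(2 * f[[1]] * f[[2]], -f[[2]]),
    from_canonical = function(a) {
      beta <- -a[[2]]
      c(mu = a[[1]] / (2 * beta), beta = beta)
    },
    canonical_jacobian = function(f) {
      matrix(c(2 * f[[2]], 0, 2 * f[[1]], -1), 2, 2)
    },
    validate = function(f) {
      bad <- character(0)
      if (!all(is.finite(unlist(f)))) bad <- c(bad, "non-finite force entry")
      else if (f[[2]] <= 0) bad <- c(bad, "relaxation rate beta must be > 0")
      bad
    },
    matrices = NULL,  # filled below (needs the finished model for closure)
    default_grid = NULL
  ))
  m$matrices <- function(forces) ou_matrices(forces[[1]], forces[[2]], sigma0)
  m$default_grid <- function(forces_list, n = 512L) {
    if (!is.list(forces_list)) forces_list <- list(forces_list)
    mus <- vapply(forces_list, function(f) f[[1]], numeric(1))
    sds <- vapply(forces_list, function(f) sigma0 / sqrt(2 * f[[2]]),
                  numeric(1))
    seq(min(mus) - 10 * max(sds), max(mus) + 10 * max(sds), length.out = n)
  }
  m
}

#' @rdname dme_model
#' @export
island_model <- function() {
  m <- new_dme_model(list(
    name = "island", dim = 3L, force_names = c("r", "lambda", "m"),
    domain = c(0, Inf),
    s = 2,
    observables = function(x) cbind(n = x, mn2h = -x^2 / 2, logn = log(x)),
    observables_grad = function(x) cbind(rep(1, length(x)), -x, 1 / x),
    observables_lap = function(x) cbind(rep(0, length(x)), rep(-1, length(x)),
                                        -1 / x^2),
    noise_g2 = function(x) x,
    noise_g2_prime = function(x) rep(1, length(x)),
    log_baseline = function(x) -log(x),
    to_canonical = function(f) unlist(f)[1:3],
    from_canonical = function(a) c(r = a[[1]], lambda = a[[2]], m = a[[3]]),
    canonical_jacobian = function(f) diag(3),
    validate = function(f) {
      f <- unlist(f)
      bad <- character(0)
      if (!all(is.finite(f))) return("non-finite force entry")
      if (f[2] <= 0) bad <- c(bad, "density regulation lambda must be > 0")
      if (f[3] <= 0.5) {
        bad <- c(bad, paste0(
          "migration rate m must exceed 1/2 for the stationary ansatz ",
          "(<1/n> diverges at the n^(2m-1) boundary; a boundary-layer ",
          "treatment is outside this package's scope)"))
      }
      bad
    },
    matrices = function(forces) island_matrices(forces),
    default_grid = NULL
  ))
  m$default_grid <- function(forces_list, n = 512L) {
    if (!is.list(forces_list)) forces_list <- list(forces_list)
    modes <- vapply(forces_list, island_mode, numeric(1))
    widths <- vapply(forces_list, function(f) sqrt(1 / (2 * f[[2]])),
                     numeric(1))
    n_max <- max(modes + 12 * widths)
    # left cutoff: density ~ n^(2m-1); pick n_lo so relative density < 1e-14
    mmin <- min(vapply(forces_list, function(f) f[[3]], numeric(1)))
    n_lo <- min(modes) * (1e-14)^(1 / (2 * mmin - 1))
    n_lo <- max(min(n_lo, min(modes) / 100), n_max * 1e-12)
    # hybrid grid: log-spaced over the power-law shoulder, linear in the bulk
    split <- min(modes) / 4
    n_log <- max(16L, round(n / 8))
    g1 <- exp(seq(log(n_lo), log(split), length.out = n_log + 1L))
    g2 <- seq(split, n_max, length.out = n - n_log)
    sort(unique(c(g1[-(n_log + 1L)], g2)))
  }
  m
}

#' Mode of the island stationary density
#'
#' Solves d/dn log u = 0 for the stationary density
#' \eqn{u \propto n^{2m-1} e^{-\lambda n^2 + 2 r n}}:
#' \eqn{n^\ast = [r + \sqrt{r^2 + 2\lambda(2m-1)}]/(2\lambda)}.
#'
#' @param forces island force vector `(r, lambda, m)`, m > 1/2.
#' @return the modal population size.
#' @export
island_mode <- function(forces) {
  f <- unlist(forces)
  (f[[1]] + sqrt(f[[1]]^2 + 2 * f[[2]] * (2 * f[[3]] - 1))) / (2 * f[[2]])
}
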