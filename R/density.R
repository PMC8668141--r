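#' Gridded probability densities
#'
#' A `gridded_density` is a probability density tabulated on a strictly
#' increasing grid inside the model domain, normalized so that its
#' trapezoidal mass is 1.
#'
#' @param grid strictly increasing state values.
#' @param values nonnegative density values at the nodes.
#' @return object of class `gridded_density` with elements `grid`, `values`
#'   and `mass` (trapezoidal integral after normalization, equal to 1 up to
#'   round-off).
#' @export
gridded_density <- function(grid, values) {
  stopifnot(length(grid) == length(values), !is.unsorted(grid, strictly = TRUE))
  if (any(values < 0)) {
    if (min(values) < -1e-12 * max(values)) {
      stop("density values must be nonnegative", call. = FALSE)
    }
    values <- pmax(values, 0)
  }
  mass <- trapz(grid, values)
  if (!is.finite(mass) || mass <= 0) stop("density has no mass", call. = FALSE)
  values <- values / mass
  structure(list(grid = grid, values = values, mass = trapz(grid, values)),
            class = "gridded_density")
}

#' @export
print.gridded_density <- function(x, ...) {
  cat(sprintf("<gridded_density> %d nodes on [%g, %g], mass %.8f\n",
              length(x$grid), min(x$grid), max(x$grid), x$mass))
  invisible(x)
}

# log of the unnormalized stationary density nu(x) exp[s alpha_c . A(x)]
log_unnorm_density <- function(model, forces, x) {
  ac <- model$to_canonical(forces)
  model$log_baseline(x) + model$s * drop(model$observables(x) %*% ac)
}

# stationary ansatz evaluated on given nodes without boundary diagnostics
# (used when tabulating the DME ansatz on a solver grid for KL comparison)
dme_ansatz_on <- function(model, forces, nodes) {
  lu <- log_unnorm_density(model, forces, nodes)
  gridded_density(nodes, exp(lu - max(lu)))
}

# locate the mode of the unnormalized stationary density (coarse grid scan
# refined by golden-section search)
density_mode <- function(model, forces) {
  if (model$name == "island") return(island_mode(forces))
  g <- model$default_grid(list(forces), n = 256L)
  i <- which.max(log_unnorm_density(model, forces, g))
  lo <- g[max(1L, i - 2L)]; hi <- g[min(length(g), i + 2L)]
  stats::optimize(function(x) log_unnorm_density(model, forces, x),
                  c(lo, hi), maximum = TRUE)$maximum
}

#' Stationary density of a model at fixed forces
#'
#' Evaluates the exponential-family stationary density
#' \eqn{\bar u_\alpha(x) = \nu(x) e^{s \alpha_c \cdot A(x)} / Z} on a grid
#' and normalizes it by trapezoidal quadrature. The default grid is wide
#' enough that the density at the boundary is below \eqn{10^{-12}} of the
#' peak; a warning is issued if a user-supplied grid truncates visible mass.
#'
#' @param model a [dme_model].
#' @param forces force vector in the natural parameterization.
#' @param grid optional state grid; defaults to `model$default_grid`.
#' @param n number of nodes for the default grid.
#' @return a [gridded_density()].
#' @export
stationary_density <- function(model, forces, grid = NULL, n = 512L) {
  assert_valid_forces(model, forces)
  if (is.null(grid)) grid <- model$default_grid(list(forces), n = n)
  lu <- log_unnorm_density(model, forces, grid)
  v <- exp(lu - max(lu))
  if (v[1] > 1e-10 || v[length(v)] > 1e-10) {
    warning("stationary density is not negligible at the grid boundary; ",
            "consider a wider grid", call. = FALSE)
  }
  gridded_density(grid, v)
}

#' Log partition function
#'
#' Computes \eqn{\log Z = \log \int \nu(x) e^{s \alpha_c \cdot A(x)} dx} by
#' adaptive quadrature in log space: the integrand is shifted by its maximum
#' before exponentiation so that no overflow occurs even when the exponent
#' is large (e.g. island parameters with large \eqn{r^2/\lambda}).
#'
#' Together with the observables, \eqn{\log Z} acts as a cumulant generating
#' function: its gradient in the exponent coordinates \eqn{\theta = s
#' \alpha_c} is \eqn{\langle A \rangle} and its Hessian is the observable
#' covariance.
#'
#' @inheritParams stationary_density
#' @return scalar \eqn{\log Z}.
#' @export
log_partition <- function(model, forces) {
  assert_valid_forces(model, forces)
  mode <- density_mode(model, forces)
  M <- log_unnorm_density(model, forces, mode)
  I <- quad(function(x) exp(log_unnorm_density(model, forces, x) - M),
            model$domain[1], model$domain[2], split = mode)
  if (!is.finite(I) || I <= 0) {
    stop("partition integral diverged or vanished", call. = FALSE)
  }
  M + log(I)
}

#' Expectations of the model observables
#'
#' Computes \eqn{\langle A_i \rangle} either under a tabulated density
#' (trapezoidal quadrature) or under the stationary density at a force
#' vector (adaptive quadrature).
#'
#' @param model a [dme_model].
#' @param density a [gridded_density()]; mutually exclusive with `forces`.
#' @param forces force vector; mutually exclusive with `density`.
#' @return named numeric vector of length `model$dim`.
#' @export
moments_of <- function(model, density = NULL, forces = NULL) {
  if (is.null(density) == is.null(forces)) {
    stop("supply exactly one of `density` or `forces`", call. = FALSE)
  }
  if (!is.null(density)) {
    stopifnot(inherits(density, "gridded_density"))
    if (model$name == "island") {
      edge <- density$values[1] * (density$grid[2] - density$grid[1])
      if (edge > 1e-6) {
        warning("non-negligible mass at the left grid edge; ",
                "<1/n>-type quantities are unreliable", call. = FALSE)
      }
    }
    A <- model$observables(density$grid)
    out <- apply(A * density$values, 2, function(col)
      trapz(density$grid, col))
  } else {
    assert_valid_forces(model, forces)
    mode <- density_mode(model, forces)
    logZ <- log_partition(model, forces)
    w <- function(x) exp(log_unnorm_density(model, forces, x) - logZ)
    out <- vapply(seq_len(model$dim), function(j) {
      quad(function(x) model$observables(x)[, j] * w(x),
           model$domain[1], model$domain[2], split = mode)
    }, numeric(1))
  }
  names(out) <- colnames(model$observables(if (model$domain[1] >= 0) 1 else 0))
  out
}

#' Kullback-Leibler divergence between gridded densities
#'
#' Computes \eqn{\mathrm{KL}(u \| u_{ref}) = \int u \log(u/u_{ref})\,dx} by
#' trapezoidal quadrature. When the grids differ, the coarser density is
#' interpolated onto the finer grid. Nodes where \eqn{u < 10^{-15}}
#' contribute zero. The divergence is the sign-flipped relative entropy used
#' as the model-reduction error metric: nonnegative, and zero iff the
#' densities agree almost everywhere.
#'
#' @param u,u_ref [gridded_density()] objects.
#' @return scalar KL divergence (>= 0 up to quadrature round-off of about
#'   1e-10).
#' @export
relative_entropy_kl <- function(u, u_ref) {
  stopifnot(inherits(u, "gridded_density"), inherits(u_ref, "gridded_density"))
  if (!isTRUE(all.equal(u$grid, u_ref$grid))) {
    grid <- if (length(u$grid) >= length(u_ref$grid)) u$grid else u_ref$grid
    grid <- grid[grid >= max(min(u$grid), min(u_ref$grid)) &
                 grid <= min(max(u$grid), max(u_ref$grid))]
    u <- gridded_density(grid, interp_density(u$grid, u$values, grid))
    u_ref <- gridded_density(grid, interp_density(u_ref$grid, u_ref$values,
                                                  grid))
  }
  uu <- u$values; rr <- u_ref$values
  bad <- uu > 1e-10 & rr < 1e-14
  if (any(bad)) {
    rng <- range(u$grid[bad])
    stop(sprintf(
      "support mismatch: u has mass where u_ref vanishes (x in [%g, %g])",
      rng[1], rng[2]), call. = FALSE)
  }
  f <- ifelse(uu < 1e-15, 0, uu * log(pmax(uu, 1e-300) / pmax(rr, 1e-300)))
  trapz(u$grid, f)
}
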