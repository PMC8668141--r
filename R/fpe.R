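#' Cell-centered grid for the Fokker-Planck solver
#'
#' Builds a uniform cell-centered grid whose bounds leave negligible
#' (< 1e-10) stationary mass outside for every force level supplied. For
#' the island model the left bound is placed at a small positive cutoff:
#' the density vanishes as \eqn{n^{2m-1}} at 0 for \eqn{m > 1/2}, so a
#' zero-flux wall at \eqn{n_{lo} > 0} is consistent and avoids the
#' coordinate singularity of the diffusion coefficient \eqn{g^2 = n}.
#'
#' @param model a [dme_model].
#' @param forces_list a force vector or list of force vectors the solution
#'   will visit.
#' @param n_cells number of cells (>= 200 recommended).
#' @return object of class `fpe_grid`: list with `nodes` (cell centers),
#'   `h` (cell width), `bounds`, `model`.
#' @export
fpe_grid <- function(model, forces_list, n_cells = 400L) {
  if (!is.list(forces_list)) forces_list <- list(forces_list)
  g <- model$default_grid(forces_list, n = 512L)
  lo <- min(g); hi <- max(g)
  if (model$domain[1] == 0) {
    # analytic mass below n_lo scales as n_lo^(2m); keep it < 1e-10
    mmin <- min(vapply(forces_list, function(f) f[[3]], numeric(1)))
    modes <- vapply(forces_list, island_mode, numeric(1))
    lo <- min(modes) * (1e-10)^(1 / (2 * mmin))
  }
  h <- (hi - lo) / n_cells
  structure(list(nodes = lo + (seq_len(n_cells) - 0.5) * h, h = h,
                 bounds = c(lo, hi), model = model$name),
            class = "fpe_grid")
}

# advection coefficient of the flux form J = B_adv u - D u' :
#   drift a(x) = (g^2 s / 2) * sum_i alpha_c,i A_i'(x);  D = g^2/2;
#   B_adv = a - D'.
fpe_coefficients <- function(model, forces, x) {
  ac <- model$to_canonical(forces)
  a <- (model$noise_g2(x) * model$s / 2) *
    drop(model$observables_grad(x) %*% ac)
  D <- model$noise_g2(x) / 2
  list(B = a - model$noise_g2_prime(x) / 2, D = D)
}

# Chang-Cooper tridiagonal operator. Returns the three diagonals of M in
# du/dt = M u with zero flux through both boundaries. The exponential
# fitting weight delta = 1/P - 1/(e^P - 1) (P = h B/D at the face) makes
# the discrete stationary state reproduce exp(int B/D) exactly at the
# nodes, so positivity and detailed balance hold at the scheme level.
fpe_operator <- function(model, forces, grid) {
  x <- grid$nodes; h <- grid$h; nc <- length(x)
  xf <- (x[-nc] + x[-1]) / 2                      # interior faces
  cf <- fpe_coefficients(model, forces, xf)
  P <- h * cf$B / cf$D
  delta <- ifelse(abs(P) < 1e-8, 0.5, 1 / P - 1 / expm1(P))
  # J_{i+1/2} = B [ (1-delta) u_i + delta u_{i+1} ] - (D/h)(u_{i+1} - u_i)
  a_lo <- cf$B * (1 - delta) + cf$D / h           # coefficient of u_i
  a_hi <- cf$B * delta - cf$D / h                 # coefficient of u_{i+1}
  # du_i/dt = (J_{i-1/2} - J_{i+1/2}) / h
  lower <- a_lo / h                                # effect of u_{i-1} on i
  upper <- -a_hi / h                               # effect of u_{i+1} on i
  diag <- numeric(nc)
  diag[1] <- -a_lo[1] / h
  diag[nc] <- a_hi[nc - 1] / h
  if (nc > 2) diag[2:(nc - 1)] <- (a_hi[1:(nc - 2)] - a_lo[2:(nc - 1)]) / h
  list(lower = lower, diag = diag, upper = upper)
}

tridiag_mult <- function(op, u) {
  nc <- length(u)
  out <- op$diag * u
  out[-1] <- out[-1] + op$lower * u[-nc]
  out[-nc] <- out[-nc] + op$upper * u[-1]
  out
}

#' Discrete stationary state of the Fokker-Planck scheme
#'
#' Zero flux through every face of the Chang-Cooper discretization forces
#' \eqn{u_{i+1}/u_i = e^{P_i}} with \eqn{P_i = h B/D} at the face; the
#' recursion is evaluated in log space and normalized. Agrees with the
#' analytic stationary density at second order in the cell width.
#'
#' @param model a [dme_model].
#' @param forces force vector.
#' @param grid an [fpe_grid()].
#' @return numeric vector of cell-center densities (sums to 1/h).
#' @export
fpe_stationary <- function(model, forces, grid) {
  x <- grid$nodes; h <- grid$h; nc <- length(x)
  xf <- (x[-nc] + x[-1]) / 2
  cf <- fpe_coefficients(model, forces, xf)
  lg <- c(0, cumsum(h * cf$B / cf$D))
  u <- exp(lg - max(lg))
  u / (sum(u) * h)
}

#' Solve the 1D Fokker-Planck equation
#'
#' Method-of-lines integration of \eqn{\partial_t u = -\partial_x J},
#' \eqn{J = B_{adv} u - D\,\partial_x u}, with a positivity-preserving
#' Chang-Cooper (exponential-fitting) flux discretization, discrete
#' zero-flux boundaries, and stiff `deSolve::lsoda` time stepping on a
#' banded Jacobian. The integrator restarts at every protocol switch time.
#' Total discrete mass is monitored at every output time and a drift beyond
#' `1e-6` aborts the run; densities more negative than round-off (1e-8
#' relative to the peak) abort, smaller excursions are clipped to zero.
#'
#' @param model a [dme_model].
#' @param protocol a [drive_protocol].
#' @param initial initial density: a [gridded_density()], a force vector
#'   (stationary start) or a vector of cell values on `grid`.
#' @param times increasing output times.
#' @param grid an [fpe_grid()].
#' @param rtol,atol integration tolerances.
#' @return object of class `fpe_solution`: list with `times`, `dens`
#'   (matrix, one row per time, cell-center values), `grid`, `mass_error`.
#' @export
solve_fpe <- function(model, protocol, initial, times, grid,
                      rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(grid, "fpe_grid"), !is.unsorted(times, strictly = TRUE))
  x <- grid$nodes; h <- grid$h; nc <- length(x)
  u0 <- if (inherits(initial, "gridded_density")) {
    interp_density(initial$grid, initial$values, x)
  } else if (length(initial) == nc) {
    as.numeric(initial)
  } else {
    lu <- log_unnorm_density(model, initial, x)
    exp(lu - max(lu))
  }
  u0 <- u0 / (sum(u0) * h)
  segment_op <- NULL
  deriv <- function(t, u, parms) {
    op <- if (!is.null(segment_op)) segment_op
          else fpe_operator(model, protocol$evaluate(t), grid)
    list(tridiag_mult(op, u))
  }
  t0 <- times[1]; t1 <- times[length(times)]
  bounds <- sort(unique(c(t0, protocol$switch_times(t0, t1), t1)))
  piecewise_const <- protocol$kind %in%
    c("constant", "step", "square_wave", "custom_table")
  dens <- matrix(NA_real_, length(times), nc)
  if (times[1] == t0) dens[1, ] <- u0
  u <- u0
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; b <- bounds[k + 1]
    segment_op <- NULL
    if (piecewise_const) {
      segment_op <- fpe_operator(model, protocol$evaluate(a), grid)
    }
    idx <- which(times > a & times <= b)
    seg <- sort(unique(c(a, times[idx], b)))
    sol <- deSolve::lsoda(u, seg, deriv, parms = NULL, rtol = rtol,
                          atol = atol, jactype = "bandint",
                          bandup = 1L, banddown = 1L)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("FPE integration failed on [%g, %g]", a, b), call. = FALSE)
    }
    if (length(idx)) dens[idx, ] <- sol[match(times[idx], sol[, 1]), -1]
    u <- sol[nrow(sol), -1]
  }
  mass <- rowSums(dens) * h
  mass_err <- max(abs(mass - 1))
  if (mass_err > 1e-6) {
    stop(sprintf("FPE mass drift %.3e exceeds 1e-6", mass_err), call. = FALSE)
  }
  if (min(dens) < -1e-8 * max(dens)) {
    stop(sprintf("FPE produced negative density %.3e", min(dens)),
         call. = FALSE)
  }
  dens[dens < 0] <- 0          # clip time-stepping round-off
  structure(list(times = times, dens = dens, grid = grid,
                 mass_error = mass_err),
            class = "fpe_solution")
}

#' @export
print.fpe_solution <- function(x, ...) {
  cat(sprintf(
    "<fpe_solution '%s'> %d times, %d cells, max |mass - 1| = %.2e\n",
    x$grid$model, length(x$times), length(x$grid$nodes), x$mass_error))
  invisible(x)
}

#' Observable means of an FPE solution
#'
#' @param sol an `fpe_solution`.
#' @param model the matching [dme_model].
#' @return data.frame with `t` and one column per observable.
#' @export
fpe_moments <- function(sol, model) {
  A <- model$observables(sol$grid$nodes)
  out <- sol$dens %*% A * sol$grid$h
  colnames(out) <- colnames(A)
  data.frame(t = sol$times, out)
}

# density snapshot as a gridded_density
fpe_density_at <- function(sol, t) {
  i <- which.min(abs(sol$times - t))
  gridded_density(sol$grid$nodes, pmax(sol$dens[i, ], 0))
}

#' Birth-death transition-matrix reference for the island model
#'
#' Continuous-time birth-death chain on \eqn{n = 0..N_{max}} with rates
#' \deqn{b_n = m + n(1+r)/2,\qquad d_n = n(1-r)/2 + \lambda n^2,}
#' a nonnegative decomposition whose drift \eqn{b_n - d_n = n(r - \lambda n)
#' + m} matches the island SDE exactly while the per-step fluctuation
#' \eqn{b_n + d_n = m + n + \lambda n^2} only approximates the SDE's
#' variance \eqn{n} (an acknowledged discrepancy of the discrete
#' reference). Requires \eqn{|r| \le 1} for nonnegative rates.
#'
#' @param forces island force vector `c(r, lambda, m)`.
#' @param N_max truncation (should exceed 3x the carrying capacity).
#' @return object of class `birth_death_chain`: list with `b`, `d`
#'   (rates, index n = 0..N_max) and `N_max`.
#' @export
build_birth_death <- function(forces, N_max) {
  f <- unlist(forces)
  if (abs(f[1]) > 1) {
    stop("|r| > 1: the rate decomposition b = m + n(1+r)/2, ",
         "d = n(1-r)/2 + lambda n^2 would go negative", call. = FALSE)
  }
  n <- 0:N_max
  structure(list(b = f[3] + n * (1 + f[1]) / 2,
                 d = n * (1 - f[1]) / 2 + f[2] * n^2,
                 N_max = N_max, forces = f),
            class = "birth_death_chain")
}

#' Stationary distribution of a birth-death chain
#'
#' Detailed balance \eqn{\pi_{n+1} = \pi_n b_n / d_{n+1}}, evaluated in log
#' space and normalized.
#'
#' @param chain a [build_birth_death()] chain.
#' @return probability vector over `0:N_max`.
#' @export
bd_stationary <- function(chain) {
  lg <- c(0, cumsum(log(chain$b[-length(chain$b)]) - log(chain$d[-1])))
  p <- exp(lg - max(lg))
  p / sum(p)
}

#' Integrate the birth-death master equation
#'
#' Solves \eqn{dp/dt = p\,Q} for the tridiagonal generator of the chain
#' (rows sum to zero, reflecting truncation at `N_max`) with stiff banded
#' `lsoda`. With a protocol, the generator is rebuilt at each switch time.
#'
#' @param chain a `birth_death_chain`, or a function `t -> chain` together
#'   with `switch_times`.
#' @param p0 initial pmf over `0:N_max` (sums to 1).
#' @param times increasing output times.
#' @param switch_times protocol discontinuities (when `chain` is a
#'   function).
#' @param rtol,atol tolerances.
#' @return list with `times`, `pmf` (matrix, one row per time).
#' @export
solve_master <- function(chain, p0, times, switch_times = numeric(0),
                         rtol = 1e-10, atol = 1e-14) {
  stopifnot(abs(sum(p0) - 1) < 1e-8)
  get_chain <- if (inherits(chain, "birth_death_chain")) {
    function(t) chain
  } else {
    chain
  }
  deriv_for <- function(ch) {
    b <- ch$b; d <- ch$d; N <- ch$N_max + 1L
    function(t, p, parms) {
      dp <- -(b + d) * p
      dp[1] <- dp[1] + d[1] * p[1]          # no death out of 0 (d_0 = 0 anyway)
      dp[N] <- dp[N] + b[N] * p[N]          # truncation: no birth out of N_max
      dp[-1] <- dp[-1] + b[-N] * p[-N]
      dp[-N] <- dp[-N] + d[-1] * p[-1]
      list(dp)
    }
  }
  t0 <- times[1]; t1 <- times[length(times)]
  bounds <- sort(unique(c(t0, switch_times[switch_times > t0 &
                                             switch_times < t1], t1)))
  pmf <- matrix(NA_real_, length(times), length(p0))
  pmf[1, ] <- p0
  p <- p0
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; b2 <- bounds[k + 1]
    f <- deriv_for(get_chain(a))
    idx <- which(times > a & times <= b2)
    seg <- sort(unique(c(a, times[idx], b2)))
    sol <- deSolve::lsoda(p, seg, f, parms = NULL, rtol = rtol, atol = atol,
                          jactype = "bandint", bandup = 1L, banddown = 1L)
    if (length(idx)) pmf[idx, ] <- sol[match(times[idx], sol[, 1]), -1]
    p <- sol[nrow(sol), -1]
  }
  tail_mass <- max(pmf[, ncol(pmf)])
  if (tail_mass > 1e-6) {
    stop(sprintf("pmf mass %.2e at N_max: increase the truncation",
                 tail_mass), call. = FALSE)
  }
  if (max(abs(rowSums(pmf) - 1)) > 1e-8) {
    stop("master-equation mass not conserved", call. = FALSE)
  }
  list(times = times, pmf = pmf)
}
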