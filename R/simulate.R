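#' Seeded Euler-Maruyama trajectory ensembles
#'
#' Simulates the OU SDE \eqn{dx = \beta(\mu - x)dt + \sigma_0 d\xi} or the
#' island SDE \eqn{dn = [n(r-\lambda n)+m]dt + \sqrt{n}\,d\xi} for an
#' ensemble of trajectories on a fixed time step, recording the states at
#' `save_times`. Ensembles are bit-reproducible given
#' `(seed, dt, n_traj, protocol)`: a single `set.seed(seed)` governs both
#' the initial draw and all Wiener increments, with the whole ensemble
#' stepped as one vectorized sweep.
#'
#' Initial states are drawn from the stationary density at `init` (via
#' [sample_stationary()]; for the OU model that is the Gaussian
#' \eqn{N(\mu_0, \sigma_0^2/(2\beta_0))}), or may be supplied explicitly.
#' Euler-Maruyama can overshoot the island state below 0 even though the
#' true \eqn{m > 1/2} process stays positive; the step is followed by
#' reflection \eqn{n \leftarrow |n|}, which preserves the stationary mass
#' near the boundary better than clamping to 0 (clamping creates an
#' artificial atom there).
#'
#' @param mu0,beta0,sigma0 OU initial stationary parameters and noise
#'   magnitude.
#' @param protocol [drive_protocol] for the applied forces.
#' @param n_traj number of trajectories.
#' @param dt Euler-Maruyama time step.
#' @param t_max final time.
#' @param seed integer RNG seed.
#' @param save_times times at which states are recorded (snapped to the step
#'   grid); default every 0.1 time units.
#' @param noise set `FALSE` to switch the diffusion off (deterministic
#'   limit, used for scheme verification).
#' @param init for [simulate_island()]: either a DME-valid force vector
#'   (stationary initialization) or a numeric vector of `n_traj` explicit
#'   initial states.
#' @return object of class `trajectory_ensemble`: list with `times`,
#'   `states` (`n_traj` x `length(times)` matrix), `dt`, `seed`, `model`,
#'   `protocol`.
#' @name simulate_sde
NULL

new_ensemble <- function(model, times, states, dt, seed, protocol) {
  structure(list(model = model, times = times, states = states, dt = dt,
                 seed = seed, protocol = protocol),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble '%s'> %d paths, %d saved times, dt = %g\n",
              x$model, nrow(x$states), length(x$times), x$dt))
  invisible(x)
}

# shared stepping loop: `drift(x, f)` and `diff_sd(x)` give per-state drift
# and noise standard deviation (per unit sqrt(dt)); `post` fixes up states
# after each step (island reflection).
em_run <- function(model_name, protocol, x, dt, t_max, save_times, noise,
                   drift, diff_sd, post, seed) {
  n_steps <- ceiling(t_max / dt - 1e-9)
  save_idx <- unique(pmin(pmax(round(save_times / dt), 0L), n_steps))
  times <- save_idx * dt
  states <- matrix(NA_real_, length(x), length(times))
  ptr <- 1L
  if (0L %in% save_idx) { states[, ptr] <- x; ptr <- ptr + 1L }
  sq <- sqrt(dt)
  for (s in seq_len(n_steps)) {
    f <- protocol$evaluate((s - 1) * dt)
    x <- x + drift(x, f) * dt +
      (if (noise) diff_sd(x) * sq * stats::rnorm(length(x)) else 0)
    x <- post(x)
    if (s %in% save_idx) { states[, ptr] <- x; ptr <- ptr + 1L }
  }
  new_ensemble(model_name, times, states, dt, seed, protocol)
}

#' @rdname simulate_sde
#' @export
simulate_ou <- function(mu0, beta0, sigma0, protocol, n_traj = 3000L,
                        dt = 0.01, t_max = 10, seed = 1L,
                        save_times = NULL, noise = TRUE) {
  stopifnot(dt > 0, n_traj >= 1, beta0 > 0, sigma0 > 0)
  if (is.null(save_times)) save_times <- seq(0, t_max, by = 0.1)
  set.seed(seed)
  x <- stats::rnorm(n_traj, mu0, sigma0 / sqrt(2 * beta0))
  if (!noise) x <- rep(mu0, n_traj)
  em_run("ou", protocol, x, dt, t_max, save_times, noise,
         drift = function(x, f) f[[2]] * (f[[1]] - x),
         diff_sd = function(x) sigma0,
         post = identity, seed = seed)
}

#' @rdname simulate_sde
#' @export
simulate_island <- function(protocol, n_traj = 3000L, dt = 0.01, t_max = 40,
                            seed = 1L, init, save_times = NULL,
                            noise = TRUE) {
  stopifnot(dt > 0, n_traj >= 1)
  if (is.null(save_times)) save_times <- seq(0, t_max, by = 0.1)
  set.seed(seed)
  if (length(init) == n_traj && n_traj > 3) {
    x <- as.numeric(init)
  } else if (length(init) == 3) {
    x <- sample_stationary(island_model(), init, n_traj, seed = NULL)
  } else {
    stop("`init` must be an island force vector or n_traj explicit states",
         call. = FALSE)
  }
  if (!noise && length(init) == 3) x <- rep(island_mode(init), n_traj)
  check_lambda <- function(f) {
    if (f[[2]] <= 0) stop("lambda <= 0: explosive drift", call. = FALSE)
  }
  check_lambda(protocol$evaluate(0))
  em_run("island", protocol, x, dt, t_max, save_times, noise,
         drift = function(x, f) { check_lambda(f)
           x * (f[[1]] - f[[2]] * x) + f[[3]] },
         diff_sd = function(x) sqrt(pmax(x, 0)),
         post = abs, seed = seed)
}

#' Sample from a stationary density by inverse-CDF
#'
#' Tabulates the stationary density at `forces` on a fine grid, forms the
#' cumulative trapezoidal CDF and inverts it at uniform draws.
#'
#' @param model a [dme_model].
#' @param forces valid force vector.
#' @param n_samples number of draws.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param n_grid resolution of the CDF table.
#' @return numeric vector of samples.
#' @export
sample_stationary <- function(model, forces, n_samples, seed = 1L,
                              n_grid = 4096L) {
  assert_valid_forces(model, forces)
  if (!is.null(seed)) set.seed(seed)
  d <- stationary_density(model, forces, n = n_grid)
  dx <- diff(d$grid)
  cdf <- c(0, cumsum(dx * (d$values[-1] + d$values[-length(d$values)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], d$grid[keep], xout = stats::runif(n_samples),
                rule = 2)$y
}

#' Per-time observable means of an ensemble
#'
#' Computes, at every saved time, the ensemble mean of each model observable
#' together with its plug-in standard error
#' \eqn{\mathrm{sd}/\sqrt{n_{traj}}}.
#'
#' @param ens a `trajectory_ensemble`.
#' @param model the matching [dme_model] (defaults by the ensemble's tag).
#' @return data.frame with columns `t`, one mean and one `se_` column per
#'   observable.
#' @export
ensemble_moments <- function(ens, model = NULL) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (is.null(model)) {
    model <- if (ens$model == "ou") ou_model() else island_model()
  }
  if (model$name == "island") {
    nz <- sum(ens$states <= 0)
    if (nz > 0) {
      stop(sprintf(
        "%d non-positive population values present; <log n> undefined", nz),
        call. = FALSE)
    }
  }
  nt <- nrow(ens$states)
  out <- lapply(seq_along(ens$times), function(i) {
    A <- model$observables(ens$states[, i])
    mu <- colMeans(A)
    se <- apply(A, 2, stats::sd) / sqrt(nt)
    c(mu, stats::setNames(se, paste0("se_", names(mu))))
  })
  out <- as.data.frame(do.call(rbind, out))
  cbind(t = ens$times, out)
}
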