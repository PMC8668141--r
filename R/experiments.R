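#' Abrupt-step comparison experiment
#'
#' Starting from the stationary state at `f0`, switches the applied forces
#' abruptly to `f1` at \eqn{t = 0} and follows the relaxation with every
#' configured method: the DME effective-force ODE (initialized at
#' \eqn{\alpha^\ast(0) = \alpha_0}), the Fokker-Planck reference, and
#' optionally a seeded Euler-Maruyama ensemble. Reports per-time observables
#' from each method, the per-time divergence
#' \eqn{\mathrm{KL}(u_{FPE} \| \bar u_{\alpha^\ast})}, and density
#' snapshots.
#'
#' @param model a [dme_model].
#' @param f0,f1 pre- and post-switch force vectors (both DME-valid).
#' @param horizon final time.
#' @param n_times number of output times (uniform grid from 0).
#' @param n_traj ensemble size (0 disables the Monte-Carlo method).
#' @param dt Euler-Maruyama step.
#' @param seed ensemble seed.
#' @param n_cells FPE resolution.
#' @param snapshot_times times at which densities are recorded.
#' @param rtol,atol DME integration tolerances.
#' @return object of class `dme_comparison`: list with `times`, `forces`
#'   (DME effective forces), `observables` (per-method data.frames), `kl`
#'   (per-time KL), `snapshots`, `manifest`.
#' @export
run_step_experiment <- function(model, f0, f1, horizon = 40,
                                n_times = 201L, n_traj = 0L, dt = 0.01,
                                seed = 1L, n_cells = 400L,
                                snapshot_times = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  assert_valid_forces(model, f0); assert_valid_forces(model, f1)
  f0 <- unlist(f0); f1 <- unlist(f1)
  times <- seq(0, horizon, length.out = n_times)
  protocol <- protocol_constant(f1)

  path <- integrate_effective_forces(model, protocol, f0, times,
                                     rtol = rtol, atol = atol)
  dme_obs <- t(apply(path$forces, 1, function(f)
    moment_matrices(model, f)$A))
  dme_obs <- data.frame(t = times, dme_obs)

  grid <- fpe_grid(model, list(f0, f1), n_cells)
  fpe <- solve_fpe(model, protocol, f0, times, grid)
  fpe_obs <- fpe_moments(fpe, model)

  kl <- vapply(seq_along(times), function(i) {
    relative_entropy_kl(fpe_density_at(fpe, times[i]),
                        dme_ansatz_on(model, path$forces[i, ], grid$nodes))
  }, numeric(1))

  ens_obs <- NULL
  if (n_traj > 0) {
    ens <- if (model$name == "ou") {
      simulate_ou(f0[[1]], f0[[2]], model$sigma0, protocol, n_traj, dt,
                  horizon, seed, save_times = times)
    } else {
      simulate_island(protocol, n_traj, dt, horizon, seed, init = f0,
                      save_times = times)
    }
    ens_obs <- ensemble_moments(ens, model)
  }

  snaps <- NULL
  if (!is.null(snapshot_times)) {
    snaps <- lapply(snapshot_times, function(tt) {
      i <- which.min(abs(times - tt))
      list(t = times[i],
           fpe = fpe_density_at(fpe, times[i]),
           dme = dme_ansatz_on(model, path$forces[i, ], grid$nodes))
    })
  }

  structure(list(
    times = times, forces = path$forces,
    observables = list(dme = dme_obs, fpe = fpe_obs, ensemble = ens_obs),
    kl = kl, snapshots = snaps,
    manifest = list(model = model$name, f0 = f0, f1 = f1,
                    horizon = horizon, n_traj = n_traj, dt = dt,
                    seed = seed, n_cells = n_cells,
                    rtol = rtol, atol = atol)),
    class = "dme_comparison")
}

#' @export
print.dme_comparison <- function(x, ...) {
  cat(sprintf(
    "<dme_comparison '%s'> t in [%g, %g], methods: %s; max KL = %.3e\n",
    x$manifest$model, min(x$times), max(x$times),
    paste(names(Filter(Negate(is.null), x$observables)), collapse = ", "),
    max(x$kl)))
  invisible(x)
}

#' Irreversibility of the effective-force relaxation
#'
#' Runs the step experiment in both directions (`f0 -> f1` and
#' `f1 -> f0`, each from the respective stationary start) and measures the
#' symmetric Hausdorff distance between the two trajectories projected on
#' the first two force coordinates ((r*, lambda*) for the island model,
#' (mu*, beta*) for OU). The relaxation paths of a nonlinear reduced
#' dynamics are not time-symmetric, so the distance is far above
#' integration tolerance whenever `f0 != f1`.
#'
#' @param model a [dme_model].
#' @param f0,f1 the two force vectors.
#' @param horizon integration horizon for each direction.
#' @param n_times output resolution.
#' @param rtol,atol tolerances.
#' @return list with `forward`, `backward` (projected path matrices) and
#'   `hausdorff`.
#' @export
run_reversibility_experiment <- function(model, f0, f1, horizon = 50,
                                         n_times = 501L,
                                         rtol = 1e-8, atol = 1e-10) {
  f0 <- unlist(f0); f1 <- unlist(f1)
  times <- seq(0, horizon, length.out = n_times)
  fwd <- integrate_effective_forces(model, protocol_constant(f1), f0, times,
                                    rtol = rtol, atol = atol)
  bwd <- integrate_effective_forces(model, protocol_constant(f0), f1, times,
                                    rtol = rtol, atol = atol)
  P <- fwd$forces[, 1:2]; Q <- bwd$forces[, 1:2]
  list(forward = P, backward = Q, hausdorff = hausdorff_distance(P, Q))
}

#' Periodic-drive comparison experiment
#'
#' Integrates the DME and FPE under a periodic protocol (square wave or
#' smooth cosine-ramp alternation), starting from the stationary state at
#' the protocol's initial level. Reports per-time first observables for
#' both methods, the instantaneous-equilibrium value (the stationary mean
#' of the momentary applied forces, i.e. the adiabatic limit), a lag
#' diagnostic (the time shift maximizing the cross-correlation between the
#' DME and instantaneous-equilibrium series), and the per-time divergence
#' \eqn{\mathrm{KL}(u_{FPE} \| \bar u_{\alpha^\ast})}.
#'
#' @param model a [dme_model].
#' @param protocol a periodic [drive_protocol].
#' @param horizon final time (several periods).
#' @param n_times output resolution.
#' @param n_cells FPE resolution.
#' @param rtol,atol DME tolerances.
#' @return object of class `dme_comparison` with extra elements
#'   `equilibrium` (instantaneous-equilibrium observables) and `lag`.
#' @export
run_periodic_experiment <- function(model, protocol, horizon = 60,
                                    n_times = 601L, n_cells = 400L,
                                    rtol = 1e-8, atol = 1e-10) {
  f_start <- protocol$evaluate(0)
  times <- seq(0, horizon, length.out = n_times)
  path <- integrate_effective_forces(model, protocol, f_start, times,
                                     rtol = rtol, atol = atol)
  dme_obs <- t(apply(path$forces, 1, function(f)
    moment_matrices(model, f)$A))
  dme_obs <- data.frame(t = times, dme_obs)

  levels <- c(list(f_start), protocol$levels)
  grid <- fpe_grid(model, levels, n_cells)
  fpe <- solve_fpe(model, protocol, f_start, times, grid)
  fpe_obs <- fpe_moments(fpe, model)

  eq_obs <- t(vapply(times, function(tt)
    moment_matrices(model, protocol$evaluate(tt))$A,
    numeric(model$dim)))
  eq_obs <- data.frame(t = times, eq_obs)

  kl <- vapply(seq_along(times), function(i) {
    relative_entropy_kl(fpe_density_at(fpe, times[i]),
                        dme_ansatz_on(model, path$forces[i, ], grid$nodes))
  }, numeric(1))

  # cross-correlation lag between the DME and adiabatic first observables,
  # computed on the post-transient half of the series
  half <- times >= (max(times) / 2)
  a <- dme_obs[half, 2] - mean(dme_obs[half, 2])
  b <- eq_obs[half, 2] - mean(eq_obs[half, 2])
  dt_out <- times[2] - times[1]
  max_shift <- min(length(a) - 2L, ceiling(
    (if (is.na(protocol$period)) max(times) / 4 else protocol$period / 2) /
      dt_out))
  cors <- vapply(0:max_shift, function(s) {
    n <- length(a)
    suppressWarnings(stats::cor(a[(1 + s):n], b[1:(n - s)]))
  }, numeric(1))
  cors[is.na(cors)] <- -Inf
  lag <- (which.max(cors) - 1L) * dt_out

  structure(list(
    times = times, forces = path$forces,
    observables = list(dme = dme_obs, fpe = fpe_obs, ensemble = NULL),
    equilibrium = eq_obs, lag = lag, kl = kl, snapshots = NULL,
    manifest = list(model = model$name, kind = protocol$kind,
                    period = protocol$period, horizon = horizon,
                    n_cells = n_cells, rtol = rtol, atol = atol)),
    class = "dme_comparison")
}

#' Exponential-decay analysis of a relative-entropy series
#'
#' For each post-switch window of a KL(t) series, fits
#' \eqn{\log \mathrm{KL} \sim t} on the early sub-window running from the
#' switch until KL first drops by `drop_factor` (default 10x), and reports
#' the decay rate, the fit R^2, and whether the series later rises again
#' (non-monotonicity above the noise floor) — the signature pattern after
#' an abrupt change: a brief initial exponential drop followed by a slower
#' non-monotonous tail.
#'
#' @param times,kl the series (positive KL on the analyzed windows).
#' @param switch_times times at which the drive jumped (each opens a
#'   window; the last window closes at the end of the series).
#' @param drop_factor defines the early sub-window.
#' @param noise_floor increases below this size are ignored.
#' @return data.frame with one row per window: `t_switch`, `rate`,
#'   `r_squared`, `n_fit`, `nonmonotone`.
#' @export
analyze_error_decay <- function(times, kl, switch_times, drop_factor = 10,
                                noise_floor = 1e-12) {
  stopifnot(length(times) == length(kl))
  switch_times <- sort(switch_times)
  ends <- c(switch_times[-1], max(times))
  out <- lapply(seq_along(switch_times), function(w) {
    sel <- which(times >= switch_times[w] & times <= ends[w])
    sel <- sel[kl[sel] > 0]
    if (length(sel) < 5) {
      stop(sprintf("window at t = %g has fewer than 5 usable samples",
                   switch_times[w]), call. = FALSE)
    }
    # KL is continuous through the switch, so the decay starts at the
    # post-switch transient peak, not at the switch instant itself
    pk <- which.max(kl[sel])
    all_sel <- sel
    sel <- sel[pk:length(sel)]
    if (length(sel) < 5) sel <- all_sel
    k0 <- kl[sel[1]]
    drop_i <- which(kl[sel] <= k0 / drop_factor)
    fit_sel <- if (length(drop_i)) sel[1:max(5L, drop_i[1])] else sel
    fit_sel <- fit_sel[fit_sel <= max(sel)]
    fit <- stats::lm(log(kl[fit_sel]) ~ times[fit_sel])
    rate <- -unname(stats::coef(fit)[2])
    r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits are fine
    after <- sel[sel > max(fit_sel)]
    nonmono <- length(after) > 1 &&
      any(diff(kl[after]) > noise_floor & kl[after][-1] > noise_floor)
    data.frame(t_switch = switch_times[w], rate = rate, r_squared = r2,
               n_fit = length(fit_sel), nonmonotone = nonmono)
  })
  do.call(rbind, out)
}
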