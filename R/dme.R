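#' Moment matrices of a model at a force point
#'
#' Evaluates, under the stationary density at `forces`, the matrices that
#' drive both the raw moment dynamics and the reduced effective-force
#' dynamics:
#' \describe{
#'   \item{B}{\eqn{B_{ji} = (s/2)\langle g^2 A'_j A'_i\rangle}, the symmetric
#'     positive semidefinite Gram matrix of the observable gradients under
#'     the weight \eqn{g^2 \bar u_\alpha}. With this scaling the observable
#'     dynamics read \eqn{d\langle A\rangle/dt = B\,\alpha_c + V}.}
#'   \item{V}{\eqn{V_j = (1/2)\langle g^2 A''_j\rangle}, the drift offset.}
#'   \item{Cov}{covariance matrix of the observables.}
#'   \item{C}{sensitivity \eqn{\partial\langle A\rangle/\partial\alpha_c =
#'     s\,\mathrm{Cov}}, the (scaled) Hessian of \eqn{\log Z}; positive
#'     definite at interior force points.}
#'   \item{A}{the observable expectations themselves.}
#' }
#'
#' `method = "model"` uses the model's closed-form/semianalytic route
#' ([ou_matrices()], [island_matrices()]); `method = "quadrature"` computes
#' every entry by adaptive quadrature against the stationary density and
#' serves as the model-independent cross-check.
#'
#' @param model a [dme_model].
#' @param forces force vector (natural parameterization).
#' @param method `"model"` (default) or `"quadrature"`.
#' @return list with elements `B`, `V`, `Cov`, `C`, `A`.
#' @export
moment_matrices <- function(model, forces, method = c("model", "quadrature")) {
  method <- match.arg(method)
  assert_valid_forces(model, forces)
  if (method == "model" && !is.null(model$matrices)) {
    return(model$matrices(forces))
  }
  d <- model$dim
  mode <- density_mode(model, forces)
  logZ <- log_partition(model, forces)
  w <- function(x) exp(log_unnorm_density(model, forces, x) - logZ)
  ex <- function(f) quad(function(x) f(x) * w(x),
                         model$domain[1], model$domain[2], split = mode)
  Amean <- vapply(seq_len(d), function(j)
    ex(function(x) model$observables(x)[, j]), numeric(1))
  B <- matrix(0, d, d); Cov <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(i)) {
    B[i, j] <- B[j, i] <- (model$s / 2) * ex(function(x) {
      G <- model$observables_grad(x)
      model$noise_g2(x) * G[, i] * G[, j]
    })
    Cov[i, j] <- Cov[j, i] <- ex(function(x) {
      A <- model$observables(x)
      (A[, i] - Amean[i]) * (A[, j] - Amean[j])
    })
  }
  V <- vapply(seq_len(d), function(j) {
    0.5 * ex(function(x) model$noise_g2(x) * model$observables_lap(x)[, j])
  }, numeric(1))
  list(B = B, V = V, Cov = Cov, C = model$s * Cov, A = Amean)
}

#' Right-hand side of the effective-force dynamics
#'
#' Evaluates \eqn{d\alpha^\ast/dt = C_{\alpha^\ast}^{-1} B_{\alpha^\ast}
#' (\alpha(t) - \alpha^\ast)} in canonical coordinates via a symmetric
#' linear solve (never an explicit inverse), then maps the result back to
#' the model's natural parameterization through the Jacobian of the
#' coordinate change. At `applied == effective` the result is exactly zero:
#' constant applied forces are fixed points of the reduced dynamics.
#'
#' @param model a [dme_model].
#' @param effective current effective forces \eqn{\alpha^\ast}.
#' @param applied instantaneous applied forces \eqn{\alpha(t)}.
#' @param matrices optionally precomputed [moment_matrices()] at `effective`.
#' @return named vector \eqn{d(\mathrm{natural})/dt}.
#' @export
dme_rhs <- function(model, effective, applied, matrices = NULL) {
  assert_valid_forces(model, effective)
  if (is.null(matrices)) matrices <- moment_matrices(model, effective)
  dc <- model$to_canonical(applied) - model$to_canonical(effective)
  y_c <- sym_solve(matrices$C, matrices$B %*% dc, label = "C")
  J <- model$canonical_jacobian(effective)
  out <- drop(solve(J, y_c))
  names(out) <- model$force_names
  out
}

#' Integrate the effective-force ODE under a drive protocol
#'
#' Solves the reduced dynamics \eqn{d\alpha^\ast/dt =
#' C^{-1}B(\alpha(t)-\alpha^\ast)} with `deSolve::lsoda` (adaptive,
#' stiff-capable). The integrator is stopped and restarted at every declared
#' protocol switch time so that step-size control never straddles a jump in
#' the applied forces. Validity of the effective forces (island:
#' \eqn{m^\ast > 1/2}) is enforced at every right-hand-side evaluation; a
#' violation aborts with the time at which it occurred.
#'
#' @param model a [dme_model].
#' @param protocol a [drive_protocol] giving the applied forces.
#' @param initial initial effective forces \eqn{\alpha^\ast(0)} (natural
#'   parameterization); for a system started in equilibrium these are the
#'   pre-switch applied forces.
#' @param times increasing output times (first element is the initial time).
#' @param rtol,atol integration tolerances.
#' @param rhs_fn optional closed-form right-hand side
#'   `function(effective, applied)` overriding the generic [dme_rhs()] (the
#'   OU module uses its decoupled form).
#' @return object of class `dme_path`: list with `times`, `forces` (matrix,
#'   one row per time) and `model`.
#' @export
integrate_effective_forces <- function(model, protocol, initial, times,
                                       rtol = 1e-8, atol = 1e-10,
                                       rhs_fn = NULL) {
  stopifnot(!is.unsorted(times, strictly = TRUE))
  initial <- unlist(initial)
  assert_valid_forces(model, initial)
  deriv <- function(t, y, parms) {
    names(y) <- model$force_names
    bad <- model$validate(y)
    if (length(bad)) {
      stop(sprintf("effective forces left the valid region at t = %.6g: %s",
                   t, paste(bad, collapse = "; ")), call. = FALSE)
    }
    applied <- protocol$evaluate(t)
    d <- if (is.null(rhs_fn)) dme_rhs(model, y, applied)
         else rhs_fn(y, applied)
    list(d)
  }
  t0 <- times[1]; t1 <- times[length(times)]
  switches <- protocol$switch_times(t0, t1)
  bounds <- sort(unique(c(t0, switches, t1)))
  out <- matrix(NA_real_, length(times), model$dim,
                dimnames = list(NULL, model$force_names))
  out[1, ] <- initial
  y <- initial
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; b <- bounds[k + 1]
    idx <- which(times > a & times <= b)
    seg_times <- sort(unique(c(a, times[idx], b)))
    sol <- deSolve::lsoda(y, seg_times, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("effective-force integration failed on [%g, %g]", a, b),
           call. = FALSE)
    }
    if (length(idx)) {
      out[idx, ] <- sol[match(times[idx], sol[, 1]), -1, drop = FALSE]
    }
    y <- sol[nrow(sol), -1]
    names(y) <- model$force_names
  }
  structure(list(times = times, forces = out, model = model$name),
            class = "dme_path")
}

#' @export
print.dme_path <- function(x, ...) {
  cat(sprintf("<dme_path '%s'> %d times on [%g, %g]; final forces (%s)\n",
              x$model, length(x$times), min(x$times), max(x$times),
              paste(sprintf("%.6g", x$forces[nrow(x$forces), ]),
                    collapse = ", ")))
  invisible(x)
}

#' Recover effective forces from target observable expectations
#'
#' Newton iteration for the moment-matching (first-order) conditions
#' \eqn{\langle A\rangle_{\alpha^\ast} = } `target`, using the sensitivity
#' matrix \eqn{C = s\,\mathrm{Cov}} as the exact Jacobian in canonical
#' coordinates. Steps that would leave the valid force region are halved.
#'
#' @param model a [dme_model].
#' @param target vector of target expectations (one per observable).
#' @param guess starting force vector.
#' @param tol convergence tolerance on the component-scaled residual
#'   \eqn{\max_i |\langle A_i\rangle - \mathrm{target}_i| /
#'   (1 + |\mathrm{target}_i|)}.
#' @param maxit maximum Newton iterations.
#' @details Matching the moments of an exponential-family ansatz is the
#'   convex dual of the maximum-entropy problem: the exponent coordinates
#'   \eqn{\theta = s\,\alpha_c} minimize \eqn{\log Z(\theta) - \theta\cdot
#'   \mathrm{target}}, whose gradient is \eqn{\langle A\rangle_\theta -
#'   \mathrm{target}} and whose Hessian is the observable covariance. The
#'   implementation runs box-constrained L-BFGS on this dual (the bounds
#'   keep \eqn{\theta} inside the valid region: island \eqn{\lambda > 0},
#'   \eqn{m > 1/2}; OU \eqn{\beta > 0}) and polishes the result with damped
#'   Newton steps using the covariance Hessian.
#' @return force vector (natural parameterization) matching the target.
#' @export
project_to_forces <- function(model, target, guess, tol = 1e-8, maxit = 50L) {
  target <- unname(unlist(target))
  assert_valid_forces(model, guess)
  d <- model$dim
  sc <- 1 + abs(target)
  th0 <- model$s * model$to_canonical(unlist(guess))
  if (model$name == "island") {
    lower <- c(-Inf, 1e-8, 1 + 1e-6); upper <- rep(Inf, 3)
  } else {
    lower <- rep(-Inf, d); upper <- c(Inf, -1e-8)
  }
  forces_of <- function(th) {
    f <- model$from_canonical(th / model$s)
    names(f) <- model$force_names
    f
  }
  dual <- function(th) log_partition(model, forces_of(th)) - sum(th * target)
  grad <- function(th) unname(moments_of(model, forces = forces_of(th)) -
                                target)
  opt <- stats::optim(th0, dual, grad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 200, factr = 10))
  th <- opt$par
  # Newton polish: quadratic convergence once L-BFGS is in the basin
  res <- rep(Inf, d)
  for (it in seq_len(maxit)) {
    M <- moment_matrices(model, forces_of(th))
    res <- target - M$A
    if (max(abs(res) / sc) < tol) return(forces_of(th))
    step <- drop(sym_solve(M$Cov, res, label = "Cov"))
    lam <- 1
    while (any(th + lam * step < lower) || any(th + lam * step > upper)) {
      lam <- lam / 2
      if (lam < 1e-10) {
        stop("Newton step cannot stay inside the valid force region ",
             "(target may lie outside the attainable moment cone)",
             call. = FALSE)
      }
    }
    th <- th + lam * step
  }
  stop(sprintf(
    "moment matching did not converge in %d iterations (last residual %.3e)",
    maxit, max(abs(res) / sc)), call. = FALSE)
}
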