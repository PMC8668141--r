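# Shared fixtures: the two worked parameter sets and random force samplers.

ou_fig <- list(
  mu_inf = 1, beta_inf = 0.7, sigma0 = 0.1,
  inits = list(c(mu = 1.2, beta = 0.7),
               c(mu = 0.6, beta = 0.5),
               c(mu = 0.1, beta = 0.45))
)

island_fig <- list(
  f1 = c(r = 0.1, lambda = 0.002, m = 3),
  f0 = c(r = 0.05, lambda = 0.005, m = 1)
)

rand_ou_forces <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    c(mu = stats::runif(1, -1, 1.5), beta = stats::runif(1, 0.3, 1.5)))
}

rand_island_forces <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    c(r = stats::runif(1, 0.02, 0.2),
      lambda = stats::runif(1, 5e-4, 0.01),
      m = stats::runif(1, 0.8, 5)))
}

# log Z as a function of the exponent ("Lagrange multiplier") coordinates
# theta = s * alpha_c, for finite-difference generating-function checks
logZ_theta <- function(model, theta) {
  log_partition(model, model$from_canonical(theta / model$s))
}

theta_of <- function(model, forces) model$s * model$to_canonical(forces)
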