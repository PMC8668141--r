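fig_protocol <- protocol_constant(c(mu = ou_fig$mu_inf, beta = ou_fig$beta_inf))

test_that("exact OU moments: initial condition, closed form vs ODE, limits", {
  ts <- seq(0, 10, by = 0.1)
  ex <- ou_exact_moments(0.1, 0.45, 0.1, fig_protocol, ts)
  expect_equal(ex$m[1], 0.1)
  expect_equal(ex$v[1], 0.1^2 / (2 * 0.45))
  # long-time limits
  expect_equal(ex$m[length(ts)], 1, tolerance = 1e-3)
  ex2 <- ou_exact_moments(0.1, 0.45, 0.1, fig_protocol, c(0, 50))
  expect_equal(ex2$m[2], 1, tolerance = 1e-10)
  expect_equal(ex2$v[2], 0.1^2 / (2 * 0.7), tolerance = 1e-10)
  # the (m, v) ODE route agrees with the closed form
  od <- ou_exact_moments(0.1, 0.45, 0.1, fig_protocol, c(0, 2),
                         method = "ode")
  cl <- ou_exact_moments(0.1, 0.45, 0.1, fig_protocol, c(0, 2),
                         method = "closed")
  expect_equal(od$m[2], cl$m[2], tolerance = 1e-8)
  expect_equal(od$v[2], cl$v[2], tolerance = 1e-8)
})

test_that("OU moment matrices match Gaussian moment formulas", {
  M <- ou_matrices(0, 1, 1)
  expect_equal(M$B, matrix(c(1 / 2, 0, 0, 1), 2, 2))
  expect_equal(M$C, matrix(c(1 / 2, 0, 0, 1 / 2), 2, 2))

  # C = Cov(A)/sigma0^2 under the stationary Gaussian, by quadrature
  ou <- ou_model(0.1)
  Mq <- moment_matrices(ou, c(mu = 0.6, beta = 0.8), method = "quadrature")
  Mc <- ou_matrices(0.6, 0.8, 0.1)
  expect_equal(Mc$C, Mq$Cov / 0.1^2, tolerance = 1e-8)
  expect_equal(Mc$B, Mq$B, tolerance = 1e-8)

  # the printed closed-form inverse really is the inverse
  expect_equal(Mc$C %*% Mc$Cinv, diag(2), tolerance = 1e-10)
  expect_error(ou_matrices(0.5, -1, 0.1), "beta")
})

test_that("decoupled OU rhs equals the generic engine", {
  expect_equal(unname(ou_dme_rhs(1, 0.7, 1, 0.7)), c(0, 0))
  expect_equal(unname(ou_dme_rhs(0.1, 0.45, 1, 0.7)), c(0.63, 0.225))
  ou <- ou_model(0.1)
  for (f in rand_ou_forces(20, seed = 5)) {
    app <- c(mu = f[[1]] + 0.3, beta = f[[2]] + 0.2)
    expect_equal(unname(dme_rhs(ou, f, app)),
                 unname(ou_dme_rhs(f[[1]], f[[2]], app[[1]], app[[2]])),
                 tolerance = 1e-10)
  }
  for (f in rand_ou_forces(3, seed = 6)) {
    app <- c(mu = f[[1]] - 0.2, beta = f[[2]] + 0.4)
    Mq <- moment_matrices(ou, f, method = "quadrature")
    expect_equal(unname(dme_rhs(ou, f, app, matrices = Mq)),
                 unname(ou_dme_rhs(f[[1]], f[[2]], app[[1]], app[[2]])),
                 tolerance = 1e-8)
  }
})

test_that("DME reproduces the exact OU dynamics for step and smooth drives", {
  ts <- seq(0, 10, by = 0.05)
  for (init in ou_fig$inits) {
    sol <- ou_dme_solution(init[[1]], init[[2]], 0.1, fig_protocol, ts)
    ex <- ou_exact_moments(init[[1]], init[[2]], 0.1, fig_protocol, ts)
    expect_lt(max(abs(sol$m - ex$m)), 1e-6)
    expect_lt(max(abs(sol$v - ex$v)), 1e-6)
  }
  # sinusoidal mu(t): exactness holds for arbitrary protocols
  p <- protocol_custom(function(t) c(mu = 1 + 0.3 * sin(t), beta = 0.7))
  sol <- ou_dme_solution(0.1, 0.45, 0.1, p, ts)
  ex <- ou_exact_moments(0.1, 0.45, 0.1, p, ts, method = "ode")
  expect_lt(max(abs(sol$m - ex$m)), 1e-6)
  expect_lt(max(abs(sol$v - ex$v)), 1e-6)
  # a constant protocol at the initial forces stays put
  pc <- protocol_constant(c(mu = 0.1, beta = 0.45))
  solc <- ou_dme_solution(0.1, 0.45, 0.1, pc, seq(0, 5, by = 1))
  expect_lt(max(abs(solc$m - 0.1)), 1e-9)
})

test_that("the effective-force path is independent of the noise magnitude", {
  f0 <- c(mu = 0.1, beta = 0.45); f1 <- c(mu = 1, beta = 0.7)
  ts <- seq(0, 10, by = 0.25)
  paths <- lapply(c(0.05, 0.1, 0.5), function(s0)
    integrate_effective_forces(ou_model(s0), protocol_constant(f1), f0, ts,
                               rtol = 1e-10, atol = 1e-12)$forces)
  expect_lt(max(abs(paths[[1]] - paths[[2]])), 1e-10)
  expect_lt(max(abs(paths[[2]] - paths[[3]])), 1e-10)
  # and so is the rhs itself, to round-off
  r1 <- dme_rhs(ou_model(0.05), c(mu = 0.5, beta = 0.6), f1)
  r2 <- dme_rhs(ou_model(0.5), c(mu = 0.5, beta = 0.6), f1)
  expect_lt(max(abs(r1 - r2)), 1e-12)
})

test_that("the DME Gaussian matches the FPE density in KL at snapshot times", {
  ou <- ou_model(0.1)
  f0 <- c(mu = 0.1, beta = 0.45); f1 <- c(mu = 1, beta = 0.7)
  ts <- c(0, 0.3, 1, 2, 5)
  grid <- fpe_grid(ou, list(f0, f1), 1600L)
  fpe <- solve_fpe(ou, protocol_constant(f1), f0, ts, grid)
  sol <- ou_dme_solution(0.1, 0.45, 0.1, protocol_constant(f1), ts)
  for (i in seq_along(ts)) {
    dme <- gridded_density(grid$nodes,
                           stats::dnorm(grid$nodes, sol$m[i], sqrt(sol$v[i])))
    fp <- gridded_density(grid$nodes, pmax(fpe$dens[i, ], 0))
    expect_lt(relative_entropy_kl(fp, dme), 1e-6)
  }
})
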