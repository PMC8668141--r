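test_that("ensembles are bit-reproducible under a fixed seed", {
  p <- protocol_constant(c(mu = 1, beta = 0.7))
  e1 <- simulate_ou(0.1, 0.45, 0.1, p, n_traj = 50, dt = 0.01, t_max = 1,
                    seed = 9)
  e2 <- simulate_ou(0.1, 0.45, 0.1, p, n_traj = 50, dt = 0.01, t_max = 1,
                    seed = 9)
  expect_identical(e1$states, e2$states)

  pi1 <- protocol_constant(island_fig$f1)
  i1 <- simulate_island(pi1, n_traj = 50, dt = 0.01, t_max = 1, seed = 9,
                        init = island_fig$f0)
  i2 <- simulate_island(pi1, n_traj = 50, dt = 0.01, t_max = 1, seed = 9,
                        init = island_fig$f0)
  expect_identical(i1$states, i2$states)
  s1 <- sample_stationary(island_model(), island_fig$f1, 100, seed = 4)
  s2 <- sample_stationary(island_model(), island_fig$f1, 100, seed = 4)
  expect_identical(s1, s2)
})

test_that("noise-off runs reduce to the deterministic dynamics", {
  p <- protocol_constant(c(mu = 1, beta = 0.7))
  e <- simulate_ou(0.1, 0.45, 0.1, p, n_traj = 2, dt = 1e-3, t_max = 2,
                   seed = 1, noise = FALSE, save_times = c(0, 2))
  h2 <- 1 + (0.1 - 1) * exp(-0.7 * 2)     # deterministic relaxation
  expect_equal(e$states[1, 2], h2, tolerance = 2e-3)

  # island: logistic growth with immigration ODE
  f <- island_fig$f1
  ei <- simulate_island(protocol_constant(f), n_traj = 2, dt = 1e-3,
                        t_max = 5, seed = 1, init = f, noise = FALSE,
                        save_times = c(0, 5))
  ode <- deSolve::lsoda(c(n = island_mode(f)), c(0, 5),
                        function(t, y, p) list(y * (f[1] - f[2] * y) + f[3]),
                        parms = NULL, rtol = 1e-10)
  expect_equal(ei$states[1, 2], unname(ode[2, 2]), tolerance = 1e-3)

  # m = 0, started at n = 0: absorbing state
  e0 <- simulate_island(protocol_constant(c(r = 0.1, lambda = 1, m = 0)),
                        n_traj = 10, dt = 0.01, t_max = 1, seed = 1,
                        init = rep(0, 10), save_times = c(0, 1))
  expect_true(all(e0$states == 0))
})

test_that("ensemble means agree with closed-form/quadrature references", {
  p <- protocol_constant(c(mu = 1, beta = 0.7))
  e <- simulate_ou(0.1, 0.45, 0.1, p, n_traj = 3000, dt = 0.01, t_max = 2,
                   seed = 2, save_times = c(0, 2))
  ex <- ou_exact_moments(0.1, 0.45, 0.1, p, c(0, 2))
  se <- stats::sd(e$states[, 2]) / sqrt(3000)
  expect_lt(abs(mean(e$states[, 2]) - ex$m[2]), 3 * se)
})

test_that("stationary sampling reproduces the analytic distribution", {
  ou <- ou_model(0.1)
  x <- sample_stationary(ou, c(mu = 1, beta = 0.7), 10000, seed = 8)
  v <- 0.1^2 / (2 * 0.7)
  expect_lt(abs(mean(x) - 1), 3 * sqrt(v / 10000))
  expect_lt(abs(stats::var(x) - v), 4 * v * sqrt(2 / 10000))

  isl <- island_model()
  f <- island_fig$f1
  y <- sample_stationary(isl, f, 10000, seed = 8)
  d <- stationary_density(isl, f, n = 4096)
  dx <- diff(d$grid)
  cdf <- c(0, cumsum(dx * (d$values[-1] + d$values[-length(d$values)]) / 2))
  ks <- max(abs(stats::ecdf(y)(d$grid) - cdf / max(cdf)))
  expect_lt(ks, 0.02)
})

test_that("ensemble moment tables behave", {
  p <- protocol_constant(island_fig$f1)
  ens <- simulate_island(p, n_traj = 200, dt = 0.01, t_max = 2, seed = 3,
                         init = island_fig$f1, save_times = c(0, 1, 2))
  em <- ensemble_moments(ens)
  expect_true(all(-2 * em$mn2h >= em$n^2))  # <n^2> >= <n>^2 at every time

  # a constant ensemble has zero standard errors
  ce <- simulate_island(p, n_traj = 10, dt = 0.01, t_max = 0.5, seed = 3,
                        init = rep(5, 10), save_times = 0, noise = FALSE)
  em0 <- ensemble_moments(ce)
  expect_equal(unname(unlist(em0[1, c("se_n", "se_mn2h", "se_logn")])),
               c(0, 0, 0))

  # zero states make <log n> impossible and raise a counted error
  bad <- simulate_island(p, n_traj = 10, dt = 0.01, t_max = 0.5, seed = 3,
                         init = rep(0, 10), save_times = 0, noise = FALSE)
  expect_error(ensemble_moments(bad), "non-positive")
})

test_that("halving the step leaves ensemble means within Monte-Carlo error", {
  prot <- protocol_constant(island_fig$f1)
  e1 <- simulate_island(prot, 2000, 0.01, 5, seed = 7,
                        init = island_fig$f0, save_times = c(0, 5))
  e2 <- simulate_island(prot, 2000, 0.005, 5, seed = 7,
                        init = island_fig$f0, save_times = c(0, 5))
  se <- stats::sd(e1$states[, 2]) / sqrt(2000)
  expect_lt(abs(mean(e1$states[, 2]) - mean(e2$states[, 2])), se)
})
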