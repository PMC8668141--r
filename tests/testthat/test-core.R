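test_that("stationary densities match their closed forms", {
  ou <- ou_model(0.1)
  d <- stationary_density(ou, c(mu = 1, beta = 0.7))
  v <- 0.1^2 / (2 * 0.7)
  ref <- stats::dnorm(d$grid, 1, sqrt(v))
  expect_lt(max(abs(d$values - ref)), 1e-8 * max(ref))

  isl <- island_model()
  # r = 0, lambda = 1, m = 1: u(n) = 2 n exp(-n^2) (Z = 1/2 analytically);
  # shape agrees exactly, the overall constant to trapezoid accuracy
  d2 <- stationary_density(isl, c(r = 0, lambda = 1, m = 1))
  ref2 <- 2 * d2$grid * exp(-d2$grid^2)
  shape <- ref2 / dmaxent:::trapz(d2$grid, ref2)
  expect_lt(max(abs(d2$values - shape)), 1e-10 * max(shape))
  expect_lt(abs(dmaxent:::trapz(d2$grid, ref2) - 1), 1e-4)

  f <- c(r = 0.1, lambda = 0.002, m = 3)
  d3 <- stationary_density(isl, f)
  expect_equal(d3$mass, 1, tolerance = 1e-8)
  expect_equal(d3$grid[which.max(d3$values)], island_mode(f),
               tolerance = 1e-2)
  # invalid forces are refused with the offending constraint named
  expect_error(stationary_density(isl, c(r = 0.1, lambda = 0.002, m = 0.3)),
               "1/2")
  expect_error(stationary_density(isl, c(r = 0.1, lambda = -1, m = 3)),
               "lambda")
})

test_that("log partition function matches closed forms and generates moments", {
  isl <- island_model()
  expect_equal(log_partition(isl, c(r = 0, lambda = 1, m = 1)), log(1 / 2),
               tolerance = 1e-10)

  # OU: direct quadrature of the stationary exponent, with the 1/g^2
  # baseline, gives log Z = beta mu^2/sigma0^2 + log sqrt(pi sigma0^2/beta)
  # - log sigma0^2
  mu <- 1; beta <- 0.7; s0 <- 0.1
  ou <- ou_model(s0)
  expect_equal(log_partition(ou, c(mu = mu, beta = beta)),
               beta * mu^2 / s0^2 + 0.5 * log(pi * s0^2 / beta) - log(s0^2),
               tolerance = 1e-9)

  # central finite differences of log Z in the exponent coordinates
  # reproduce <A_j> to 1e-6 relative
  f <- c(r = 0.1, lambda = 0.002, m = 3)
  th <- theta_of(isl, f)
  A <- moments_of(isl, forces = f)
  for (j in 1:3) {
    h <- 1e-3 * abs(th[j])
    e <- rep(0, 3); e[j] <- h
    fd <- (logZ_theta(isl, th + e) - logZ_theta(isl, th - e)) / (2 * h)
    expect_equal(unname(fd), unname(A[j]), tolerance = 1e-6)
  }
})

test_that("observable expectations agree across quadrature routes", {
  ou <- ou_model(0.1)
  A <- moments_of(ou, forces = c(mu = 1, beta = 0.7))
  expect_equal(unname(A), c(1, 1 + 0.01 / 1.4), tolerance = 1e-9)

  isl <- island_model()
  f <- c(r = 0.1, lambda = 0.002, m = 3)
  A2 <- moments_of(isl, forces = f)
  mo <- island_moments(f)
  expect_equal(unname(A2), c(mo$n, -mo$n2 / 2, mo$logn), tolerance = 1e-8)

  # a symmetric density about 0 has zero mean
  g <- seq(-8, 8, length.out = 2001)
  d <- gridded_density(g, stats::dnorm(g))
  expect_lt(abs(moments_of(ou, density = d)[1]), 1e-12)
})

test_that("KL divergence has the textbook properties", {
  g <- seq(-8, 9, length.out = 4001)
  u <- gridded_density(g, stats::dnorm(g, 0, 1))
  w <- gridded_density(g, stats::dnorm(g, 1, 1))
  expect_equal(relative_entropy_kl(u, u), 0, tolerance = 1e-12)
  expect_equal(relative_entropy_kl(u, w), 1 / 2, tolerance = 1e-6)

  # nonnegative on perturbed pairs, zero only at equality
  set.seed(3)
  for (i in 1:5) {
    eps <- stats::runif(1, 0.01, 0.3)
    w2 <- gridded_density(g, stats::dnorm(g, eps, 1 + eps))
    expect_gt(relative_entropy_kl(u, w2), 0)
  }

  # support mismatch is an error naming the region
  trunc <- ifelse(abs(g) < 3, stats::dnorm(g), 0)
  w3 <- gridded_density(g, trunc)
  expect_error(relative_entropy_kl(u, w3), "support mismatch")
})

test_that("dme_rhs vanishes at fixed points and matches independent routes", {
  ou <- ou_model(0.1)
  f <- c(mu = 0.8, beta = 0.9)
  expect_equal(unname(dme_rhs(ou, f, f)), c(0, 0), tolerance = 1e-14)

  # OU generic engine equals the closed decoupled form
  eff <- c(mu = 0.5, beta = 0.6); app <- c(mu = 1, beta = 0.7)
  expect_equal(unname(dme_rhs(ou, eff, app)),
               unname(ou_dme_rhs(0.5, 0.6, 1, 0.7)), tolerance = 1e-10)

  # island: linear solve equals a dense-inverse computation
  isl <- island_model()
  M <- island_matrices(c(r = 0.05, lambda = 0.005, m = 1))
  y1 <- dme_rhs(isl, c(r = 0.05, lambda = 0.005, m = 1), island_fig$f1)
  y2 <- drop(solve(M$C) %*% (M$B %*% (island_fig$f1 -
                                        c(0.05, 0.005, 1))))
  expect_true(all(is.finite(y1)))
  expect_equal(unname(y1), y2, tolerance = 1e-10)

  # an indefinite sensitivity matrix is reported with its smallest eigenvalue
  Mbad <- M; Mbad$C <- diag(c(1, 1, -1))
  expect_error(dme_rhs(isl, c(r = 0.05, lambda = 0.005, m = 1),
                       island_fig$f1, matrices = Mbad),
               "not positive definite")
})

test_that("quasi-stationarity identity B alpha + V = 0 holds at random force points", {
  isl <- island_model()
  for (f in rand_island_forces(20)) {
    M <- island_matrices(f)
    resid <- drop(M$B %*% f + M$V)
    scale <- max(abs(M$B %*% f), abs(M$V), 1)
    expect_lt(max(abs(resid)) / scale, 1e-8)
  }
  ou <- ou_model(0.1)
  for (f in rand_ou_forces(20)) {
    M <- moment_matrices(ou, f, method = "quadrature")
    resid <- drop(M$B %*% ou$to_canonical(f) + M$V)
    expect_lt(max(abs(resid)), 1e-8 * max(1, abs(f[1])))
  }
})

test_that("constant applied forces keep the effective forces constant", {
  isl <- island_model()
  f <- island_fig$f1
  p <- integrate_effective_forces(isl, protocol_constant(f), f,
                                  seq(0, 5, by = 1))
  expect_lt(max(abs(sweep(p$forces, 2, f))), 1e-9)
})

test_that("island effective forces reach the applied fixed point (t = 110)", {
  isl <- island_model()
  p <- integrate_effective_forces(isl, protocol_constant(island_fig$f1),
                                  island_fig$f0, c(0, 50, 110))
  err <- sqrt(colSums((t(p$forces) - island_fig$f1)^2))
  expect_lt(err[3], 1e-6)        # converged
  expect_lt(err[3], err[2])      # and monotonically so after the transient
  expect_lt(err[2], err[1])
})

test_that("moment matching recovers forces from observable targets", {
  ou <- ou_model(0.1)
  # OU closed form: target (m, m^2 + v) gives mu* = m, beta* = sigma0^2/(2v)
  m <- 0.7; v <- 0.004
  f <- project_to_forces(ou, c(m, m^2 + v), c(mu = 0.2, beta = 0.5))
  expect_equal(unname(f), c(m, 0.1^2 / (2 * v)), tolerance = 1e-5)

  # round trips at random points, both models
  isl <- island_model()
  for (f0 in rand_island_forces(3, seed = 11)) {
    A <- island_matrices(f0)$A
    guess <- f0 * c(1.3, 0.8, 1.2)
    rec <- project_to_forces(isl, A, guess)
    expect_equal(unname(rec), unname(f0), tolerance = 1e-6)
  }

  # an impossible target (second moment below squared mean) fails loudly
  expect_error(project_to_forces(isl, c(50, -100, log(50)),
                                 island_fig$f1))
})
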