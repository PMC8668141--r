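test_that("G(k): closed forms, dual routes, and the convergence condition", {
  # r = 0, lambda = 1, m = 1, k = 0: integral of n exp(-n^2) = 1/2
  expect_equal(island_G(0, c(0, 1, 1)), 1 / 2, tolerance = 1e-10)
  expect_equal(island_G(0, c(0, 1, 1), method = "kummer"), 1 / 2,
               tolerance = 1e-12)

  f <- island_fig$f1
  g1 <- island_G(1, f)
  expect_true(is.finite(g1) && g1 > 0)
  expect_equal(island_G(1, f, method = "kummer"), g1, tolerance = 1e-8)

  expect_error(island_G(-1, c(0.1, 0.002, 0.4)), "k \\+ 2m > 0")
  expect_error(island_G(0, c(0.1, -0.002, 3)), "lambda")
})

test_that("the <1/n> integral diverges as m approaches 1/2 from above", {
  # cutoff integrals of the G(-1) integrand n^(2m-2) e^(-lambda n^2 + 2rn):
  # for smaller excess migration the value keeps growing as the lower
  # cutoff shrinks (log-divergence at m = 1/2)
  # restrict to the boundary region (0, 1] where the singularity lives, so
  # the probe is not swamped by the regular bulk of the integrand
  cutoff_G <- function(m, lo) {
    # substitute u = log n: the near-1/n integrand becomes bounded
    stats::integrate(function(u) exp((2 * m - 1) * u - 0.002 * exp(2 * u) +
                                       0.2 * exp(u)),
                     log(lo), 0, rel.tol = 1e-10)$value
  }
  cuts <- c(1e-4, 1e-6, 1e-8)
  vals <- sapply(c(0.1, 0.01, 0.001), function(eps)
    vapply(cuts, function(lo) cutoff_G(0.5 + eps, lo), numeric(1)))
  # at fixed (smallest) cutoff the integral grows as eps -> 0+
  expect_true(all(diff(vals[3, ]) > 0))
  expect_gt(vals[3, 3] / vals[3, 1], 3)
  # increments between successive cutoffs die away for eps = 0.1 but
  # persist for eps = 0.001 (the signature of the emerging divergence)
  inc <- apply(vals, 2, diff)
  expect_lt(inc[2, 1] / inc[1, 1], 0.5)
  expect_gt(inc[2, 3] / inc[1, 3], 0.9)
})

test_that("H(k, j): definition, closed form, and dual routes", {
  f <- island_fig$f1
  expect_identical(island_H(2, 0, f), island_G(2, f))
  # r = 0, lambda = 1, m = 1: integral n log(n) exp(-n^2) = Gamma'(1)/4
  expect_equal(island_H(0, 1, c(0, 1, 1)), -0.57721566490153286 / 4,
               tolerance = 1e-8)
  # quadrature vs (1/2^j) d^j G/dm^j finite differences
  expect_equal(island_H(0, 1, f, method = "fd"), island_H(0, 1, f),
               tolerance = 1e-6)
  expect_equal(island_H(0, 2, f, method = "fd"), island_H(0, 2, f),
               tolerance = 1e-6)
})

test_that("island matrices are symmetric PSD and agree with quadrature", {
  f <- island_fig$f1
  M <- island_matrices(f)
  expect_equal(M$B, t(M$B))
  expect_true(all(eigen(M$B, symmetric = TRUE)$values > 0))
  expect_true(all(eigen(M$C, symmetric = TRUE)$values > 0))

  isl <- island_model()
  Mq <- moment_matrices(isl, f, method = "quadrature")
  expect_equal(M$Cov, Mq$Cov, tolerance = 1e-8)
  expect_equal(M$B, Mq$B, tolerance = 1e-8)
  expect_equal(M$A, Mq$A, tolerance = 1e-8, ignore_attr = TRUE)

  # plain-covariance variant is exposed behind the flag
  Mp <- island_matrices(f, scaling = "plain")
  expect_equal(Mp$C, M$C / 2)
  expect_error(island_matrices(c(0.1, 0.002, 0.4)), "1/2")
})

test_that("raw moment dynamics: stationarity, matrix route, hand arithmetic", {
  f <- island_fig$f1
  M <- island_matrices(f)
  expect_lt(max(abs(island_moment_rhs(M$moments, f))), 1e-8 * max(abs(M$V)))

  # away from stationarity the component form equals B(alpha - alpha*)
  f0 <- island_fig$f0
  M0 <- island_matrices(f0)
  rhs <- island_moment_rhs(M0$moments, f)
  expect_equal(rhs, drop(M0$B %*% (f - f0)), tolerance = 1e-10)

  hand <- island_moment_rhs(list(n = 10, n2 = 120, n3 = 0, ninv = 0),
                            c(0.1, 0.002, 3))
  expect_equal(hand[1], 0.1 * 10 - 0.002 * 120 + 3)
  expect_equal(hand[1], 3.76)
})

test_that("validity report names the threshold and diverging quantity", {
  expect_true(check_dme_validity(c(0.1, 0.002, 3))$valid)
  v5 <- check_dme_validity(c(0.1, 0.002, 0.5))
  expect_false(v5$valid)
  expect_match(v5$violations, "log-divergent")
  v4 <- check_dme_validity(c(0.1, 0.002, 0.4))
  expect_false(v4$valid)
  expect_equal(v4$diverging, "<1/n>")
  expect_false(check_dme_validity(c(0.1, -1, 3))$valid)
})

test_that("Jensen inequalities hold at random valid force points", {
  for (f in rand_island_forces(8, seed = 19)) {
    mo <- island_moments(f)
    expect_gt(mo$n2, mo$n^2)
    expect_gt(mo$ninv, 1 / mo$n)
    expect_gt(mo$n, exp(mo$logn))   # arithmetic >= geometric mean
  }
})
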