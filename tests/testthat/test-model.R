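test_that("parameter validation enforces the model's admissible region", {
  expect_s3_class(canonical_params(), "sdnam_params")
  expect_error(sdnam_params(-1, 3, 4, 0.1, 0.1, 20, 3, 8), "lam")
  expect_error(sdnam_params(10, 0, 4, 0.1, 0.1, 20, 3, 8), "k")
  expect_error(sdnam_params(10, 3, 4, 0, 0.1, 20, 3, 8), "mu")
  expect_error(sdnam_params(10, 3, 4, 0.1, 0.1, 20, 25, 8), "carrying capacity")
  expect_error(as_sdnam_params(list(lam = 1, k = 2)), "missing parameters")
  # round trip through a plain list
  p <- canonical_params()
  expect_identical(as_sdnam_params(unclass(p)), p)
})

test_that("gamma production kernel is lam times a gamma density", {
  p <- sdnam_params(10, 1, 2, 0.1, 0.1, 20, 3, 8)
  # exponential kernel (k = 1) starts at lam / theta
  expect_equal(gamma_production_rate(0, p), 5.0)
  # direct formula evaluation: 100 * t^(k-1) exp(-t/theta) / (gamma(k) theta^k)
  p2 <- sdnam_params(100, 2, 1.5, 0.1, 0.1, 20, 3, 8)
  expect_equal(gamma_production_rate(3, p2),
               100 * 3 * exp(-2) / (gamma(2) * 1.5^2), tolerance = 1e-12)
  # the kernel integrates to lam
  total <- stats::integrate(gamma_production_rate, 0, Inf, params = p2,
                            rel.tol = 1e-10)
  expect_equal(total$value, 100, tolerance = 1e-6)
  expect_error(gamma_production_rate(-1, p), ">= 0")
})

test_that("residual component decays exponentially from its initial value", {
  p <- sdnam_params(0, 3, 4, log(2), 0.1, 20, 0, 10)
  expect_equal(residual_solution(0, p), 10)
  expect_equal(residual_solution(1, p), 5)  # one half-life
  p2 <- sdnam_params(0, 3, 4, 0.1, 0.1, 20, 0, 7.3)
  expect_equal(residual_solution(20, p2), 7.3 * exp(-2), tolerance = 1e-12)
  expect_true(all(diff(residual_solution(0:50, p)) < 0))
})

test_that("persistent component follows the logistic closed form", {
  # fixed point at N and absorbing state at 0
  p_at_N <- sdnam_params(0, 3, 4, 0.1, 0.3, 40, 40, 0)
  expect_equal(persistent_solution(c(0, 5, 50), p_at_N), rep(40, 3))
  p_zero <- sdnam_params(0, 3, 4, 0.1, 0.3, 40, 0, 0)
  expect_equal(persistent_solution(c(0, 5, 50), p_zero), rep(0, 3))
  # monotone rise toward N when r > mu
  p <- sdnam_params(0, 3, 4, 0.1, 0.3, 40, 4, 0)
  x2 <- persistent_solution(seq(0, 200, 5), p)
  expect_true(all(diff(x2) >= 0))
  expect_lt(abs(x2[length(x2)] - 40), 1e-6)
})

test_that("transient component matches independent numerical routes", {
  # no production means no transient signal
  p0 <- canonical_params(); p0$lam <- 0
  expect_equal(transient_solution(c(0, 5, 50), p0), rep(0, 3))
  # clearance-free limit approaches lam * gamma CDF
  p <- sdnam_params(100, 3, 4, 1e-8, 0.1, 20, 3, 8)
  t <- c(5, 15, 40)
  expect_equal(transient_solution(t, p),
               100 * stats::pgamma(t, 3, scale = 4), tolerance = 1e-4)
  # the incomplete-gamma and quadrature branches both agree with
  # adaptive quadrature of the convolution integral
  conv <- function(ti, pp) {
    stats::integrate(function(s) {
      pp$lam * stats::dgamma(s, pp$k, scale = pp$theta) *
        exp(-pp$mu * (ti - s))
    }, 0, ti, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  cases <- list(
    sdnam_params(50, 3, 4, 0.08, 0.1, 20, 3, 8),    # closed form
    sdnam_params(300, 3, 30, 0.2, 0.1, 20, 3, 8),   # mu > 1/theta
    sdnam_params(100, 0.7, 5, 0.5, 0.1, 20, 3, 8),  # singular kernel k < 1
    sdnam_params(50, 2, 1.5, 1.8, 0.1, 20, 3, 8))   # strong clearance
  for (pp in cases) {
    ts <- c(0.5, 3, 15, 60, 120)
    ref <- vapply(ts, conv, numeric(1), pp = pp)
    expect_equal(transient_solution(ts, pp), ref, tolerance = 1e-8)
  }
})

test_that("full trajectories agree with a monolithic ODE integration", {
  for (p in list(canonical_params(),
                 sdnam_params(300, 3, 30, 0.2, 0.15, 20, 3, 8))) {
    times <- seq(0, 150, length.out = 100)
    ref <- ode_oracle(p, times)
    tr <- solve_trajectories(p, times)
    expect_lt(rel_err(tr$x1, ref$x1, floor = 1e-4), 1e-6)
    expect_lt(rel_err(tr$x2, ref$x2, floor = 1e-4), 1e-6)
    expect_lt(rel_err(tr$x3, ref$x3, floor = 1e-4), 1e-6)
  }
})

test_that("trajectory bookkeeping: pure decay, exact totals, validation", {
  p <- sdnam_params(0, 1, 1, log(2), 0.1, 20, 0, 10)
  tr <- solve_trajectories(p, c(0, 1, 2))
  expect_equal(tr$total, c(10, 5, 2.5))
  set.seed(41)
  for (i in 1:10) {
    p <- random_params()
    tr <- solve_trajectories(p, sort(stats::runif(20, 0, 200)))
    expect_identical(tr$total, tr$x1 + tr$x2 + tr$x3)
    expect_true(all(tr$x1 >= 0 & tr$x2 >= 0 & tr$x3 >= 0))
  }
  expect_error(solve_trajectories(p, c(3, 1)), "sorted")
  expect_error(solve_trajectories(p, c(-1, 2)), ">= 0")
})

test_that("transient decays at the clearance rate once production ends", {
  p <- canonical_params()
  # far beyond the kernel's support the log-slope of x1 equals -mu
  t <- seq(120, 160, 5)
  slopes <- diff(log(transient_solution(t, p))) / diff(t)
  expect_equal(mean(slopes), -p$mu, tolerance = 1e-4)
})

test_that("setting lam to zero reproduces the two-source model exactly", {
  p1 <- canonical_params_m1()
  times <- seq(0, 100, 2)
  tr <- solve_trajectories(p1, times)
  expect_identical(tr$x1, rep(0, length(times)))
  expect_identical(tr$total,
                   persistent_solution(times, p1) + residual_solution(times, p1))
})
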