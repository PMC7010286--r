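# canonical well-separated three-source parameter set used across tests:
# early transient burst (peak day 8), slow persistent rise toward 25 pM,
# 10 pM residual clearing with a ~9-day half-life
canonical_params <- function() {
  sdnam_params(lam = 400, k = 3, theta = 4, mu = 0.08,
               r = 0.15, N = 25, x2_0 = 5, x3_0 = 10)
}

# two-source (no transient) counterpart
canonical_params_m1 <- function() {
  sdnam_params(lam = 0, k = 3, theta = 4, mu = 0.06,
               r = 0.18, N = 30, x2_0 = 6, x3_0 = 12)
}

# the 12-day observation schedule used in recovery tests
recovery_days <- function() c(1, 3, 5, 8, 12, 17, 23, 30, 40, 55, 75, 100)

noise_free_series <- function(params, days = recovery_days()) {
  tibble::tibble(day = days,
                 sdnam1_pm = solve_trajectories(params, days)$total)
}

# random valid parameter draws for property-style loops
random_params <- function() {
  N <- stats::runif(1, 1, 60)
  sdnam_params(lam = stats::runif(1, 0, 500),
               k = stats::runif(1, 0.6, 12),
               theta = stats::runif(1, 0.6, 30),
               mu = stats::runif(1, 0.005, 1.5),
               r = stats::runif(1, 0, 1),
               N = N,
               x2_0 = stats::runif(1, 0, N),
               x3_0 = stats::runif(1, 0, 30))
}

# deSolve integration of the full three-compartment system
ode_oracle <- function(params, times, rtol = 1e-10, atol = 1e-12) {
  rhs <- function(t, y, parms) {
    list(c(params$lam * stats::dgamma(t, params$k, scale = params$theta) -
             params$mu * y[1],
           (params$r - params$mu) * y[2] * (1 - y[2] / params$N),
           -params$mu * y[3]))
  }
  out <- deSolve::ode(c(x1 = 0, x2 = params$x2_0, x3 = params$x3_0),
                      times, rhs, NULL, rtol = rtol, atol = atol)
  tibble::tibble(time = out[, 1], x1 = out[, 2], x2 = out[, 3],
                 x3 = out[, 4])
}

rel_err <- function(a, b, floor = 1e-8) max(abs(a - b) / pmax(abs(b), floor))
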