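#' @importFrom stats dgamma pgamma plogis
NULL

# cache for Gauss-Legendre nodes/weights on [0, 1]
.quad_env <- new.env(parent = emptyenv())

gl_rule <- function(n = 80L) {
  key <- paste0("gl", n)
  if (is.null(.quad_env[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .quad_env[[key]] <- list(x = gl$x, w = gl$w)
  }
  .quad_env[[key]]
}

#' Transient production rate of the gamma kernel
#'
#' Rate at which the transient (alloreactive donor) source releases
#' sDNAM-1 at time `t`: `lam` times the gamma density with shape `k` and
#' scale `theta`. The rate integrates to `lam` over `[0, Inf)`.
#'
#' @param t Days since transplant (vectorized, all >= 0).
#' @param params An [sdnam_params] object.
#' @return Production rate in pM/day, same length as `t`.
#' @export
gamma_production_rate <- function(t, params) {
  params <- as_sdnam_params(params)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  params$lam * dgamma(t, shape = params$k, scale = params$theta)
}

#' Residual (recipient-derived) component
#'
#' Closed-form exponential decay `x3_0 * exp(-mu * t)` of the sDNAM-1
#' present at transplant.
#'
#' @inheritParams gamma_production_rate
#' @return Concentration in pM, same length as `t`.
#' @export
residual_solution <- function(t, params) {
  params <- as_sdnam_params(params)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  params$x3_0 * exp(-params$mu * t)
}

#' Persistent (non-alloreactive donor) component
#'
#' Closed-form logistic solution with net rate `r - mu` and carrying
#' capacity `N`. `x2_0 = 0` is the absorbing state (identically zero);
#' `x2_0 = N` stays at `N`. Evaluated through the stable logistic
#' `N * plogis((r - mu) * t - log((N - x2_0) / x2_0))`.
#'
#' @inheritParams gamma_production_rate
#' @return Concentration in pM, same length as `t`.
#' @export
persistent_solution <- function(t, params) {
  params <- as_sdnam_params(params)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (params$x2_0 == 0) return(rep(0, length(t)))
  rho <- params$r - params$mu
  # log((N - x2_0)/x2_0); -Inf when x2_0 == N, giving plogis(Inf) = 1
  logC <- log(params$N - params$x2_0) - log(params$x2_0)
  params$N * plogis(rho * t - logC)
}

# log production rate: log(lam * dgamma(s; k, theta))
log_production <- function(s, params) {
  log(params$lam) + dgamma(s, shape = params$k, scale = params$theta, log = TRUE)
}

# x1 by quadrature of the convolution integral, stable in log space;
# used when the incomplete-gamma closed form is unavailable (mu >= 1/theta)
transient_quadrature <- function(t, params) {
  gl <- gl_rule()
  mu <- params$mu; k <- params$k
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    # beyond ~45 clearance e-foldings the early part of the kernel is gone
    lo <- max(0, ti - 45 / mu)
    if (lo > 0 || k >= 1) {
      s <- lo + (ti - lo) * gl$x
      (ti - lo) * sum(gl$w * exp(log_production(s, params) - mu * (ti - s)))
    } else {
      # k < 1: substitution s = t * u^(1/k) removes the s^(k-1) singularity
      s <- ti * gl$x^(1 / k)
      lc <- log(params$lam) - lgamma(k) - k * log(params$theta) +
        k * log(ti) - log(k)
      sum(gl$w * exp(lc - s / params$theta - mu * (ti - s)))
    }
  }, numeric(1))
}

#' Transient (alloreactive donor) component
#'
#' Solves `dx1/dt = lam * dgamma(t; k, theta) - mu * x1` with
#' `x1(0) = 0`, i.e. the convolution of the gamma production kernel with
#' first-order clearance. When `1/theta > mu` the solution has a closed
#' form through the regularized incomplete gamma function, evaluated in
#' log space; otherwise a fixed-order Gauss-Legendre quadrature of the
#' convolution integral is used (stable integrand, boundary-layer
#' restriction for strongly cleared kernels).
#'
#' @inheritParams gamma_production_rate
#' @return Concentration in pM, same length as `t`.
#' @export
transient_solution <- function(t, params) {
  params <- as_sdnam_params(params)
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (params$lam == 0) return(rep(0, length(t)))
  a <- 1 / params$theta - params$mu
  if (a * params$theta > 1e-10) {
    # x1(t) = lam * exp(-mu t) * (a theta)^(-k) * P(k, a t)
    out <- params$lam * exp(
      -params$mu * t - params$k * log(a * params$theta) +
        pgamma(t, shape = params$k, rate = a, log.p = TRUE)
    )
    out[t == 0] <- 0
    out
  } else {
    transient_quadrature(t, params)
  }
}

#' Evaluate all three components on a time grid
#'
#' @param params An [sdnam_params] object.
#' @param times Sorted vector of days since transplant, all >= 0.
#' @return A tibble with columns `time`, `x1` (transient), `x2`
#'   (persistent), `x3` (residual) and `total = x1 + x2 + x3`, in pM.
#' @examples
#' p <- sdnam_params(lam = 300, k = 3, theta = 4, mu = 0.06,
#'                   r = 0.15, N = 20, x2_0 = 3, x3_0 = 8)
#' solve_trajectories(p, times = seq(0, 100, by = 10))
#' @export
solve_trajectories <- function(params, times) {
  params <- as_sdnam_params(params)
  if (any(times < 0)) stop("`times` must be >= 0", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be sorted increasing", call. = FALSE)
  x1 <- transient_solution(times, params)
  x2 <- persistent_solution(times, params)
  x3 <- residual_solution(times, params)
  tibble::tibble(time = times, x1 = x1, x2 = x2, x3 = x3,
                 total = x1 + x2 + x3)
}

# total model concentration at nonnegative times (fitting workhorse)
model_total <- function(times, params) {
  transient_solution(times, params) +
    persistent_solution(times, params) +
    residual_solution(times, params)
}

# exact AUC of x1 on [0, T] from the mass balance of its ODE:
# x1(T) - x1(0) = lam * CDF(T) - mu * AUC
auc_transient <- function(params, upper) {
  if (params$lam == 0) return(0)
  mass_in <- params$lam * pgamma(upper, shape = params$k, scale = params$theta)
  (mass_in - transient_solution(upper, params)) / params$mu
}

# exact AUC of x2 on [0, T]: N/rho * [softplus(rho T - logC) - softplus(-logC)]
auc_persistent <- function(params, upper) {
  if (params$x2_0 == 0) return(0)
  if (params$x2_0 == params$N) return(params$N * upper)
  rho <- params$r - params$mu
  if (abs(rho) * upper < 1e-10) return(params$x2_0 * upper)
  logC <- log(params$N - params$x2_0) - log(params$x2_0)
  softplus <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  params$N / rho * (softplus(rho * upper - logC) - softplus(-logC))
}
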