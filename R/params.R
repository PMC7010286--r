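#' Model parameters for the three-source sDNAM-1 model
#'
#' Bundles the eight quantities that parameterize the dynamical model: the
#' transient source (gamma-kernel production with first-order clearance),
#' the persistent source (logistic growth), and the recipient-derived
#' residual (exponential decay). The same clearance rate `mu` acts on the
#' transient and residual components and enters the persistent component's
#' effective growth rate `r - mu`, which is what makes the full model an
#' eight-parameter model.
#'
#' @param lam Total mass delivered by the transient production kernel, in
#'   pM. The kernel is `lam` times a unit gamma density, so the production
#'   rate integrates to `lam` over `[0, Inf)`. `lam = 0` turns the
#'   transient source off (the two-source model restriction).
#' @param k Gamma shape of the production kernel (dimensionless, > 0).
#' @param theta Gamma scale of the production kernel, in days (> 0). The
#'   production rate peaks near `(k - 1) * theta` for `k > 1`.
#' @param mu First-order clearance rate, per day (> 0). The serum
#'   half-life is `log(2) / mu`.
#' @param r Intrinsic growth rate of the persistent source, per day
#'   (>= 0); net logistic rate is `r - mu`.
#' @param N Carrying capacity of the persistent source, pM (> 0).
#' @param x2_0 Persistent-source concentration at day 0, pM
#'   (`0 <= x2_0 <= N`). Exactly 0 keeps the persistent source at 0
#'   forever (logistic absorbing state).
#' @param x3_0 Residual recipient-derived concentration at day 0, pM
#'   (>= 0).
#'
#' @return An object of class `sdnam_params`: a named list of the eight
#'   validated parameters.
#' @examples
#' p <- sdnam_params(lam = 300, k = 3, theta = 4, mu = 0.06,
#'                   r = 0.15, N = 20, x2_0 = 3, x3_0 = 8)
#' p
#' @export
sdnam_params <- function(lam, k, theta, mu, r, N, x2_0, x3_0) {
  p <- list(lam = lam, k = k, theta = theta, mu = mu,
            r = r, N = N, x2_0 = x2_0, x3_0 = x3_0)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad)) {
    stop("parameters must be finite numeric scalars: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p$lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  if (p$k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (p$theta <= 0) stop("`theta` must be > 0", call. = FALSE)
  if (p$mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  if (p$r < 0) stop("`r` must be >= 0", call. = FALSE)
  if (p$N <= 0) stop("`N` must be > 0", call. = FALSE)
  if (p$x2_0 < 0) stop("`x2_0` must be >= 0", call. = FALSE)
  if (p$x2_0 > p$N) stop("`x2_0` must not exceed the carrying capacity `N`", call. = FALSE)
  if (p$x3_0 < 0) stop("`x3_0` must be >= 0", call. = FALSE)
  structure(p, class = "sdnam_params")
}

#' @export
print.sdnam_params <- function(x, ...) {
  cat("<sdnam_params>\n")
  cat(sprintf("  transient : lam = %.4g pM, k = %.4g, theta = %.4g d\n",
              x$lam, x$k, x$theta))
  cat(sprintf("  persistent: r = %.4g /d, N = %.4g pM, x2_0 = %.4g pM\n",
              x$r, x$N, x$x2_0))
  cat(sprintf("  residual  : x3_0 = %.4g pM\n", x$x3_0))
  cat(sprintf("  clearance : mu = %.4g /d (half-life %.3g d)\n",
              x$mu, log(2) / x$mu))
  invisible(x)
}

#' Coerce a named vector or list to `sdnam_params`
#'
#' @param x A named numeric vector, named list, or one-row data frame with
#'   entries `lam, k, theta, mu, r, N, x2_0, x3_0`.
#' @return An `sdnam_params` object.
#' @export
as_sdnam_params <- function(x) {
  if (inherits(x, "sdnam_params")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  x <- as.list(x)
  need <- c("lam", "k", "theta", "mu", "r", "N", "x2_0", "x3_0")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "), call. = FALSE)
  do.call(sdnam_params, lapply(x[need], as.numeric))
}

param_names <- function() c("lam", "k", "theta", "mu", "r", "N", "x2_0", "x3_0")
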