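#' One-choice drift-diffusion parameters
#'
#' Constructs and validates the parameter quadruple of the one-choice
#' (single-boundary) drift-diffusion model: threshold `a`, relative starting
#' point `z`, drift rate `v` and non-decision time `t0`.  The diffusion
#' coefficient is fixed at 1, the package's single scaling convention;
#' `a` and `v` are therefore in evidence units (per second for `v`) and all
#' times are in seconds.
#'
#' `z` is a dimensionless fraction of `a`: accumulation starts at `z * a` and
#' terminates at `a`, so the remaining distance is `a * (1 - z)` and the
#' decision time is Wald (inverse-Gaussian) distributed with mean
#' `a * (1 - z) / v` and shape `(a * (1 - z))^2`.
#'
#' @param a decision threshold, strictly positive.
#' @param z relative starting point, in the open interval (0, 1).
#' @param v drift rate, strictly positive.
#' @param t0 non-decision time in seconds, non-negative.
#' @return an object of class `ddm_params`.
#' @examples
#' p <- ddm_params(a = 8.86, z = 0.43, v = 8.48, t0 = 0.28)
#' mean_rt(p)  # 0.28 + 8.86 * 0.57 / 8.48
#' @export
ddm_params <- function(a, z, v, t0) {
  stopifnot(length(a) == 1L, length(z) == 1L, length(v) == 1L,
            length(t0) == 1L)
  if (!is.finite(a) || a <= 0) stop("'a' must be finite and > 0")
  if (!is.finite(z) || z <= 0 || z >= 1) stop("'z' must lie in (0, 1)")
  if (!is.finite(v) || v <= 0) stop("'v' must be finite and > 0")
  if (!is.finite(t0) || t0 < 0) stop("'t0' must be finite and >= 0")
  structure(list(a = a, z = z, v = v, t0 = t0), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "one-choice DDM parameters: a = %.4g, z = %.4g, v = %.4g, t0 = %.4g s\n",
    x$a, x$z, x$v, x$t0))
  cat(sprintf("  implied mean RT %.4g s (decision time %.4g s)\n",
              mean_rt(x), x$a * (1 - x$z) / x$v))
  invisible(x)
}

# Wald parameters (mu, lambda) implied by a ddm_params object
ddm_wald <- function(params) {
  k <- params$a * (1 - params$z)
  list(mu = k / params$v, lambda = k^2)
}

#' First-passage density of the one-choice diffusion
#'
#' The density of the observed response time under a `ddm_params` object:
#' a shifted Wald with location `a (1 - z) / v`, shape `(a (1 - z))^2` and
#' shift `t0`.  Zero for `rt <= t0`.
#'
#' @param rt vector of response times in seconds.
#' @param params a [ddm_params()] object.
#' @param log logical; return the log density.
#' @return density values (per second).
#' @export
ddm_density <- function(rt, params, log = FALSE) {
  stopifnot(inherits(params, "ddm_params"))
  w <- ddm_wald(params)
  dshiftwald(rt, mu = w$mu, lambda = w$lambda, shift = params$t0, log = log)
}

#' Analytic CDF of the one-choice diffusion response time
#'
#' @inheritParams ddm_density
#' @return cumulative probabilities.
#' @export
ddm_cdf <- function(rt, params) {
  stopifnot(inherits(params, "ddm_params"))
  w <- ddm_wald(params)
  pshiftwald(rt, mu = w$mu, lambda = w$lambda, shift = params$t0)
}

#' Log-likelihood of response times under the one-choice diffusion
#'
#' Numerically stable sum of log first-passage densities.  Any `rt <= t0`
#' yields `-Inf` (not an error); an empty vector yields 0.
#'
#' @inheritParams ddm_density
#' @param rts vector of response times in seconds.
#' @return scalar log-likelihood.
#' @export
ddm_loglik <- function(rts, params) {
  if (length(rts) == 0L) return(0)
  if (any(!is.finite(rts))) stop("all response times must be finite")
  ll <- ddm_density(rts, params, log = TRUE)
  if (any(ll == -Inf)) return(-Inf)
  sum(ll)
}

#' Sample response times from the one-choice diffusion
#'
#' Exact draws of `t0` plus a Wald first-passage time, via the
#' Michael-Schucany-Haas transformation.
#'
#' @inheritParams ddm_density
#' @param n number of draws, at least 1.
#' @param seed optional integer; when given, draws come from a private RNG
#'   stream seeded with it and the caller's stream is untouched.
#' @return `n` response times in seconds, all `> t0`.
#' @export
ddm_sample <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "ddm_params"), n >= 1)
  w <- ddm_wald(params)
  with_seed(seed, rshiftwald(n, mu = w$mu, lambda = w$lambda,
                             shift = params$t0))
}

#' Closed-form mean response time
#'
#' `t0 + a (1 - z) / v`, the shift plus the Wald mean.
#'
#' @inheritParams ddm_density
#' @return mean response time in seconds.
#' @export
mean_rt <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  params$t0 + params$a * (1 - params$z) / params$v
}

#' Closed-form variance of the response time
#'
#' `mu^3 / lambda` with `mu = a (1 - z) / v`, `lambda = (a (1 - z))^2`;
#' the shift `t0` does not contribute.
#'
#' @inheritParams ddm_density
#' @return variance in seconds squared.
#' @export
var_rt <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  w <- ddm_wald(params)
  w$mu^3 / w$lambda
}
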