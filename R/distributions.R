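#' Shifted-Wald (shifted inverse-Gaussian) distribution
#'
#' Density, distribution function and random generation for the first-passage
#' time of a single-boundary diffusion with unit diffusion coefficient:
#' an inverse-Gaussian (Wald) distribution with mean `mu` and shape `lambda`,
#' shifted right by `shift` (the non-decision time).
#'
#' For a one-choice diffusion with threshold `a`, relative start point `z`,
#' drift `v` and non-decision time `t0`, the decision time is inverse-Gaussian
#' with `mu = a * (1 - z) / v` and `lambda = (a * (1 - z))^2`, and the observed
#' response time is that first-passage time plus `t0`.
#'
#' @param x,q vector of quantiles (response times, same unit as `mu`).
#' @param n number of draws.
#' @param mu mean of the unshifted inverse-Gaussian (strictly positive).
#' @param lambda shape parameter (strictly positive).
#' @param shift location shift (non-negative).
#' @param log,log.p logical; return log density / log probability.
#'
#' @return `dshiftwald` the density (0 for `x <= shift`), `pshiftwald` the
#'   distribution function, `rshiftwald` a vector of `n` draws `> shift`.
#'
#' @details Random generation uses the Michael-Schucany-Haas transformation
#' (exact, no rejection loop).  The upper tail of the CDF is evaluated on the
#' log scale so that the `exp(2 * lambda / mu)` factor cannot overflow.
#'
#' @examples
#' x <- rshiftwald(1000, mu = 0.6, lambda = 25, shift = 0.28)
#' all(x > 0.28)
#' integrate(dshiftwald, 0.28, Inf, mu = 0.6, lambda = 25, shift = 0.28)
#' @export
dshiftwald <- function(x, mu, lambda, shift = 0, log = FALSE) {
  stopifnot(all(mu > 0), all(lambda > 0), all(shift >= 0))
  d <- x - shift
  ok <- is.finite(d) & d > 0
  out <- rep(-Inf, length(d))
  if (any(ok)) {
    dd <- d[ok]
    mu_ok <- if (length(mu) > 1L) mu[ok] else mu
    la_ok <- if (length(lambda) > 1L) lambda[ok] else lambda
    out[ok] <- 0.5 * (log(la_ok) - log(2 * pi) - 3 * log(dd)) -
      la_ok * (dd - mu_ok)^2 / (2 * mu_ok^2 * dd)
  }
  if (log) out else exp(out)
}

#' @rdname dshiftwald
#' @export
pshiftwald <- function(q, mu, lambda, shift = 0, log.p = FALSE) {
  stopifnot(all(mu > 0), all(lambda > 0), all(shift >= 0))
  d <- q - shift
  n <- max(length(d), length(mu), length(lambda))
  d <- rep_len(d, n); mu <- rep_len(mu, n); lambda <- rep_len(lambda, n)
  p <- numeric(n)
  ok <- is.finite(d) & d > 0
  if (any(ok)) {
    dd <- d[ok]; m <- mu[ok]; l <- lambda[ok]
    r <- sqrt(l / dd)
    term1 <- pnorm(r * (dd / m - 1))
    # second term computed in logs: exp(2 lambda / mu) * pnorm(-r (d/mu + 1))
    term2 <- exp(2 * l / m + pnorm(-r * (dd / m + 1), log.p = TRUE))
    p[ok] <- pmin(1, term1 + term2)
  }
  p[is.infinite(d) & d > 0] <- 1
  if (log.p) log(p) else p
}

#' @rdname dshiftwald
#' @export
rshiftwald <- function(n, mu, lambda, shift = 0) {
  stopifnot(n >= 0, all(mu > 0), all(lambda > 0), all(shift >= 0))
  mu <- rep_len(mu, n); lambda <- rep_len(lambda, n)
  y <- rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- runif(n)
  flip <- u > mu / (mu + x)
  x[flip] <- mu[flip]^2 / x[flip]
  x + shift
}

## ---- truncated normal helpers -------------------------------------------

#' Truncated normal distribution
#'
#' Density, random generation and mean of a normal distribution truncated to
#' `[lower, upper]`.  Generation is by inversion of the CDF, so draws are
#' exact and loop-free; with `sd = 0` the point mass at `mean` is returned
#' (after checking it lies inside the interval).
#'
#' @param x vector of quantiles.
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal (`sd >= 0`).
#' @param lower,upper truncation bounds.
#' @param log logical; return log density.
#' @return density values, draws, or the truncated mean.
#' @keywords internal
#' @export
dtruncnorm <- function(x, mean = 0, sd = 1, lower = -Inf, upper = Inf,
                       log = FALSE) {
  stopifnot(all(sd > 0), lower < upper)
  lz <- log(pnorm(upper, mean, sd) - pnorm(lower, mean, sd))
  out <- ifelse(x >= lower & x <= upper,
                dnorm(x, mean, sd, log = TRUE) - lz, -Inf)
  if (log) out else exp(out)
}

#' @rdname dtruncnorm
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(all(sd >= 0), lower < upper)
  if (all(sd == 0)) {
    if (any(mean < lower | mean > upper))
      stop("degenerate truncated normal: mean outside [lower, upper]")
    return(rep_len(mean, n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' @rdname dtruncnorm
#' @export
etruncnorm <- function(mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(all(sd >= 0), lower < upper)
  if (all(sd == 0)) return(mean)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

# total probability mass of N(mean, sd) inside [lower, upper]
truncnorm_mass <- function(mean, sd, lower, upper) {
  if (sd == 0) return(as.numeric(mean >= lower & mean <= upper))
  pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards; with seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
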