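#' Split-R-hat convergence diagnostic
#'
#' The potential scale reduction factor computed after splitting each chain
#' in half, so that within-chain drift is detected even with a single chain.
#'
#' @param x matrix of draws, one column per chain.
#' @return scalar R-hat (`NA` for a constant parameter).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])))
  m <- ncol(halves); nn <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size of one chain via Geyer's initial positive sequence
ess_one <- function(x) {
  n <- length(x)
  if (n < 8L || var(x) == 0) return(NA_real_)
  rho <- as.vector(acf(x, lag.max = min(n - 2L, 500L),
                       plot = FALSE, demean = TRUE)$acf)[-1]
  npair <- floor(length(rho) / 2)
  tau <- 1
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (!is.finite(g) || g <= 0) break
    tau <- tau + 2 * g
  }
  min(n, n / tau)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size, summed over chains.
#'
#' @param x matrix of draws, one column per chain.
#' @return scalar effective sample size.
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  sum(apply(x, 2, ess_one), na.rm = TRUE)
}
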