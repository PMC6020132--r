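#' Model variants of the hierarchical one-choice diffusion
#'
#' The four competing hypotheses about the group difference in go RT, encoded
#' as which parameters have group-specific group-level means: model 1 frees
#' `z` and `v`; model 2 frees `z` only (prior-precision hypothesis); model 3
#' frees `v` only (sensory-precision hypothesis); model 4 frees `a` only
#' (strategic-slowing hypothesis).  The non-decision time `t0` is always
#' shared across groups.
#'
#' @param id integer 1-4, or `NULL` when `free_by_group` is given directly.
#' @param free_by_group character subset of `c("z", "v", "a")`; overrides
#'   `id` (useful for a fully shared null model via `character(0)`).
#' @return list of class `model_spec` with `id` and `free_by_group`.
#' @export
model_spec <- function(id = NULL, free_by_group = NULL) {
  canon <- list(`1` = c("z", "v"), `2` = "z", `3` = "v", `4` = "a")
  if (is.null(free_by_group)) {
    if (is.null(id) || !id %in% 1:4)
      stop("'id' must be 1, 2, 3 or 4 unless free_by_group is given")
    free_by_group <- canon[[as.character(id)]]
  } else {
    if (!all(free_by_group %in% c("z", "v", "a")))
      stop("free_by_group must be a subset of {z, v, a}; t0 is always shared")
    if (is.null(id)) id <- NA_integer_
  }
  structure(list(id = id, free_by_group = free_by_group),
            class = "model_spec")
}

#' Weakly informative default priors
#'
#' Group-level mean priors are truncated normals at the scale the task's
#' published summary statistics imply: `a ~ N(5, 5^2)` on (0, Inf),
#' `z ~ N(0.5, 0.25^2)` on (0, 1), `v ~ N(5, 5^2)` on (0, Inf),
#' `t0 ~ N(0.3, 0.3^2)` on (0, Inf) seconds.  Between-subject SDs have
#' half-normal priors (scale 1; 0.2 for `z`).  Every entry can be
#' overridden.
#'
#' @return nested list keyed by parameter, each with `mu_loc`, `mu_scale`,
#'   `lower`, `upper`, `sd_scale`.
#' @export
default_priors <- function() {
  list(
    a  = list(mu_loc = 5,   mu_scale = 5,    lower = 0, upper = Inf,
              sd_scale = 1),
    z  = list(mu_loc = 0.5, mu_scale = 0.25, lower = 0, upper = 1,
              sd_scale = 0.2),
    v  = list(mu_loc = 5,   mu_scale = 5,    lower = 0, upper = Inf,
              sd_scale = 1),
    t0 = list(mu_loc = 0.3, mu_scale = 0.3,  lower = 0, upper = Inf,
              sd_scale = 1)
  )
}

#' MCMC configuration
#'
#' @param n_samples draws retained per chain after the adaptation phase
#'   (the first `burn_in` of them are discarded from all summaries).
#' @param burn_in number of initial retained draws to discard
#'   (`< n_samples`).
#' @param n_chains number of chains (>= 1; more chains enable split-R-hat
#'   across chains).
#' @param adapt length of the preliminary adaptation phase during which
#'   random-walk proposal scales are tuned towards 20-50% acceptance;
#'   adaptation is frozen before any retained draw, so the short burn-in is
#'   honest.
#' @param seed integer master seed; chain `c` uses `seed + c - 1`.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 10000, burn_in = 200, n_chains = 4,
                        adapt = 500, seed = 1L) {
  stopifnot(n_samples >= 2, burn_in >= 0, burn_in < n_samples,
            n_chains >= 1, adapt >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains),
                 adapt = as.integer(adapt), seed = as.integer(seed)),
            class = "mcmc_config")
}

## ---- internal sampler machinery -----------------------------------------

PARAMS4 <- c("a", "z", "v", "t0")

trans_par <- function(x, p) switch(p, a = log(x), z = qlogis(x),
                                   v = log(x), t0 = x)
itrans_par <- function(e, p) switch(p, a = exp(e), z = plogis(e),
                                    v = exp(e), t0 = e)
logjac_par <- function(x, p) switch(p, a = log(x), z = log(x * (1 - x)),
                                    v = log(x), t0 = rep(0, length(x)))

param_domain <- function(p) switch(p, a = c(0, Inf), z = c(0, 1),
                                   v = c(0, Inf), t0 = c(0, Inf))

# Per-subject log-likelihood of go RTs under subject parameter matrix
# theta: S x 4 (a, z, v, t0); rt: trial vector (s); si: subject index/trial.
# With a finite `ceiling` (seconds) the density is right-truncated at it:
# each subject's contribution is normalized by the first-passage mass below
# the ceiling, the correct likelihood for data retained under a known
# slow-RT exclusion rule (ntr: retained trials per subject).
ll_by_subject <- function(theta, rt, si, S, ceiling = NULL, ntr = NULL) {
  k <- theta[, 1] * (1 - theta[, 2])
  mu <- k / theta[, 3]
  lam <- k * k
  d <- rt - theta[si, 4]
  lf <- rep(-Inf, length(d))
  ok <- d > 0
  if (any(ok)) {
    dd <- d[ok]; m <- mu[si][ok]; l <- lam[si][ok]
    lf[ok] <- 0.5 * (log(l) - log(2 * pi) - 3 * log(dd)) -
      l * (dd - m)^2 / (2 * m^2 * dd)
  }
  out <- rep(-Inf, S)
  sums <- rowsum(lf, si)
  out[as.integer(rownames(sums))] <- sums[, 1]
  if (!is.null(ceiling)) {
    lmass <- pshiftwald(ceiling, mu, lam, theta[, 4], log.p = TRUE)
    out <- ifelse(is.finite(lmass), out - ntr * lmass, -Inf)
  }
  out
}

# normalized truncated-normal log density summed over x (mu_vec recycled)
lp_truncnorm_sum <- function(x, mu_vec, sigma, lo, up) {
  z <- pnorm(up, mu_vec, sigma) - pnorm(lo, mu_vec, sigma)
  if (any(z <= 0)) return(-Inf)
  sum(dnorm(x, mu_vec, sigma, log = TRUE)) - sum(log(z))
}

# Method-of-moments initialization for one subject's go RTs (seconds).
# t0_init is a cohort-common shift: starting every subject at (nearly) the
# same non-decision time keeps group RT differences in the accumulation
# parameters, where the hierarchy can attribute them, rather than seeding a
# spurious group split in the weakly identified subject t0s.
init_subject <- function(rt, t0_init) {
  t0 <- min(t0_init, 0.9 * min(rt))
  d <- rt - t0
  mu_d <- mean(d)
  var_d <- max(var(d), 1e-6)
  k <- sqrt(max(mu_d^3 / var_d, 1e-3))
  v <- k / mu_d
  z <- 0.4
  a <- k / (1 - z)
  c(a = a, z = z, v = v, t0 = t0)
}

run_chain <- function(rt, si, S, gi, G, free, priors, config, chain_seed,
                      ceiling = NULL, ntr = NULL) {
  set.seed(chain_seed)
  n_keep <- config$n_samples
  n_adapt <- config$adapt
  ll_fun <- function(th) ll_by_subject(th, rt, si, S, ceiling, ntr)

  ## --- initialization ------------------------------------------------
  t0_init <- 0.8 * min(rt)
  theta <- t(vapply(split(rt, si), init_subject, numeric(4),
                    t0_init = t0_init))
  theta <- theta[order(as.integer(rownames(theta))), , drop = FALSE]
  # chain-specific jitter for overdispersed starts
  theta[, 1] <- theta[, 1] * exp(0.05 * rnorm(S))
  theta[, 3] <- theta[, 3] * exp(0.05 * rnorm(S))
  theta[, 2] <- plogis(qlogis(theta[, 2]) + 0.1 * rnorm(S))
  theta[, 4] <- pmin(theta[, 4] * runif(S, 0.9, 1.0),
                     0.95 * vapply(split(rt, si), min, numeric(1)))

  mu <- list(); sigma <- list()
  for (j in seq_along(PARAMS4)) {
    p <- PARAMS4[j]
    if (p %in% free) {
      mu[[p]] <- vapply(seq_len(G),
                        function(g) mean(theta[gi == g, j]), numeric(1))
    } else mu[[p]] <- mean(theta[, j])
    s0 <- sd(theta[, j])
    if (!is.finite(s0)) s0 <- 0          # single-subject fits
    sigma[[p]] <- max(s0, 0.05 * priors[[p]]$sd_scale)
  }

  ll <- ll_fun(theta)
  if (any(!is.finite(ll)))
    stop("non-finite initial likelihood; check the trial table")

  ## --- proposal scales ------------------------------------------------
  step_subj <- matrix(0.15, S, 4)
  step_subj[, 4] <- 0.02               # t0 on identity scale (seconds)
  step_ridge <- rep(0.3, S)
  step_shift <- rep(0.02, S)
  step_mpr <- rep(0.03, S)
  step_scale_all <- 0.05
  step_shift_all <- 0.01
  step_mpr_all <- 0.02
  step_mu <- list()
  for (p in PARAMS4) step_mu[[p]] <- rep(0.2 * priors[[p]]$mu_scale,
                                         length(mu[[p]]))
  step_sigma <- lapply(PARAMS4, function(p) 0.3)
  names(step_sigma) <- PARAMS4

  ## --- storage ---------------------------------------------------------
  mu_names <- unlist(lapply(PARAMS4, function(p)
    if (p %in% free) paste0("mu_", p, "[g", seq_len(G), "]")
    else paste0("mu_", p)))
  sig_names <- paste0("sigma_", PARAMS4)
  subj_names <- as.vector(outer(PARAMS4, seq_len(S),
                                function(p, s) paste0(p, "[", s, "]")))
  cn <- c(mu_names, sig_names, subj_names)
  draws <- matrix(NA_real_, n_keep, length(cn),
                  dimnames = list(NULL, cn))
  deviance <- numeric(n_keep)

  target_acc <- 0.3
  n_iter <- n_adapt + n_keep

  for (it in seq_len(n_iter)) {
    adapting <- it <= n_adapt
    gam <- if (adapting) min(0.5, it^(-0.6)) else 0

    ## 1. subject-level parameters, vectorized across subjects
    for (j in seq_along(PARAMS4)) {
      p <- PARAMS4[j]
      cur <- theta[, j]
      eta <- trans_par(cur, p)
      prop <- itrans_par(eta + step_subj[, j] * rnorm(S), p)
      dom <- param_domain(p)
      valid <- is.finite(prop) & prop > dom[1] & prop < dom[2]
      if (p == "t0") valid <- valid & prop >= 0
      theta_prop <- theta
      theta_prop[, j] <- ifelse(valid, prop, cur)
      llp <- ll_fun(theta_prop)
      mu_vec <- if (p %in% free) mu[[p]][gi] else rep(mu[[p]], S)
      lp_cur <- -(cur - mu_vec)^2 / (2 * sigma[[p]]^2)
      lp_prop <- -(prop - mu_vec)^2 / (2 * sigma[[p]]^2)
      logr <- (llp - ll) + (lp_prop - lp_cur) +
        (logjac_par(prop, p) - logjac_par(cur, p))
      logr[!valid] <- -Inf
      acc <- valid & is.finite(logr) & log(runif(S)) < logr
      theta[acc, j] <- prop[acc]
      ll[acc] <- llp[acc]
      if (adapting)
        step_subj[, j] <- step_subj[, j] * exp(gam * (acc - target_acc))
    }

    ## 2. ridge move: rescale a holding a(1 - z) fixed (likelihood-free;
    ##    the (a, z) pair is only prior-identified in one-choice data)
    a_cur <- theta[, 1]; z_cur <- theta[, 2]
    k <- a_cur * (1 - z_cur)
    a_prop <- a_cur * exp(step_ridge * rnorm(S))
    z_prop <- 1 - k / a_prop
    valid <- z_prop > 0 & z_prop < 1
    mu_a <- if ("a" %in% free) mu[["a"]][gi] else rep(mu[["a"]], S)
    mu_z <- if ("z" %in% free) mu[["z"]][gi] else rep(mu[["z"]], S)
    logr <- (-(a_prop - mu_a)^2 + (a_cur - mu_a)^2) / (2 * sigma[["a"]]^2) +
      (-(z_prop - mu_z)^2 + (z_cur - mu_z)^2) / (2 * sigma[["z"]]^2)
    acc <- valid & is.finite(logr) & log(runif(S)) < logr
    theta[acc, 1] <- a_prop[acc]
    theta[acc, 2] <- z_prop[acc]
    if (adapting)
      step_ridge <- step_ridge * exp(gam * (acc - target_acc))

    ## 2b. shift move: trade non-decision time against drift rate holding
    ##     the mean RT fixed (t0 and v ride a strong likelihood ridge)
    k <- theta[, 1] * (1 - theta[, 2])
    mu_w <- k / theta[, 3]
    delta <- step_shift * rnorm(S)
    t0_prop <- theta[, 4] + delta
    mu_prop <- mu_w - delta
    valid <- t0_prop >= 0 & mu_prop > 0
    v_prop <- ifelse(valid, k / mu_prop, theta[, 3])
    t0_prop <- ifelse(valid, t0_prop, theta[, 4])
    theta_prop <- theta
    theta_prop[, 3] <- v_prop
    theta_prop[, 4] <- t0_prop
    llp <- ll_fun(theta_prop)
    mu_v <- if ("v" %in% free) mu[["v"]][gi] else rep(mu[["v"]], S)
    mu_t <- rep(mu[["t0"]], S)
    logr <- (llp - ll) +
      (-(v_prop - mu_v)^2 + (theta[, 3] - mu_v)^2) / (2 * sigma[["v"]]^2) +
      (-(t0_prop - mu_t)^2 + (theta[, 4] - mu_t)^2) /
        (2 * sigma[["t0"]]^2) +
      2 * (log(v_prop) - log(theta[, 3]))
    acc <- valid & is.finite(logr) & log(runif(S)) < logr
    theta[acc, 3] <- v_prop[acc]
    theta[acc, 4] <- t0_prop[acc]
    ll[acc] <- llp[acc]
    if (adapting)
      step_shift <- step_shift * exp(gam * (acc - target_acc))

    ## 2b2. moment-preserving ridge move: shift t0 and move (z, v) so the
    ##      subject's RT mean AND variance are unchanged (k and v follow
    ##      mu* = mu - delta at fixed Wald variance).  This is the direction
    ##      the likelihood is nearly blind to; acceptance is prior-driven.
    ##      Jacobian of (z, v) <-> (mu, var) is proportional to mu / var^2,
    ##      so a shear in (mu, var, t0) contributes log(mu*/mu).
    k <- theta[, 1] * (1 - theta[, 2])
    mu_w <- k / theta[, 3]
    var_w <- mu_w / theta[, 3]^2
    delta <- step_mpr * rnorm(S)
    t0_prop <- theta[, 4] + delta
    mu_prop <- mu_w - delta
    valid <- t0_prop >= 0 & mu_prop > 0
    mu_prop <- ifelse(valid, mu_prop, mu_w)
    t0_prop <- ifelse(valid, t0_prop, theta[, 4])
    v_prop <- sqrt(mu_prop / var_w)
    k_prop <- mu_prop * v_prop
    z_prop <- 1 - k_prop / theta[, 1]
    valid <- valid & z_prop > 0 & z_prop < 1
    theta_prop <- theta
    theta_prop[, 2] <- ifelse(valid, z_prop, theta[, 2])
    theta_prop[, 3] <- ifelse(valid, v_prop, theta[, 3])
    theta_prop[, 4] <- ifelse(valid, t0_prop, theta[, 4])
    llp <- ll_fun(theta_prop)
    mu_z_vec <- if ("z" %in% free) mu[["z"]][gi] else rep(mu[["z"]], S)
    mu_v_vec <- if ("v" %in% free) mu[["v"]][gi] else rep(mu[["v"]], S)
    mu_t_vec <- rep(mu[["t0"]], S)
    logr <- (llp - ll) +
      (-(theta_prop[, 2] - mu_z_vec)^2 + (theta[, 2] - mu_z_vec)^2) /
        (2 * sigma[["z"]]^2) +
      (-(theta_prop[, 3] - mu_v_vec)^2 + (theta[, 3] - mu_v_vec)^2) /
        (2 * sigma[["v"]]^2) +
      (-(theta_prop[, 4] - mu_t_vec)^2 + (theta[, 4] - mu_t_vec)^2) /
        (2 * sigma[["t0"]]^2) +
      log(mu_prop / mu_w)
    acc <- valid & is.finite(logr) & log(runif(S)) < logr
    theta[acc, 2] <- z_prop[acc]
    theta[acc, 3] <- v_prop[acc]
    theta[acc, 4] <- t0_prop[acc]
    ll[acc] <- llp[acc]
    if (adapting)
      step_mpr <- step_mpr * exp(gam * (acc - target_acc))

    ## 2c. cohort scale move: multiply every a (subjects, group means,
    ##     group SD) by c and shrink every 1 - z by 1/c, keeping all
    ##     a_i (1 - z_i) and hence the likelihood fixed.  Lets the whole
    ##     hierarchy travel the prior-identified a/z ridge.
    eps <- step_scale_all * rnorm(1)
    cc <- exp(eps)
    a_new <- theta[, 1] * cc
    z_new <- 1 - (1 - theta[, 2]) / cc
    mu_a_new <- mu[["a"]] * cc
    mu_z_new <- 1 - (1 - mu[["z"]]) / cc
    sig_a_new <- sigma[["a"]] * cc
    sig_z_new <- sigma[["z"]] / cc
    pr_a <- priors[["a"]]; pr_z <- priors[["z"]]
    if (all(z_new > 0) && all(mu_z_new > pr_z$lower) &&
        all(mu_z_new < pr_z$upper) &&
        all(mu_a_new > pr_a$lower) && all(mu_a_new < pr_a$upper)) {
      mu_a_vec <- if ("a" %in% free) mu[["a"]][gi] else rep(mu[["a"]], S)
      mu_z_vec <- if ("z" %in% free) mu[["z"]][gi] else rep(mu[["z"]], S)
      mu_a_vec_new <- if ("a" %in% free) mu_a_new[gi] else
        rep(mu_a_new, S)
      mu_z_vec_new <- if ("z" %in% free) mu_z_new[gi] else
        rep(mu_z_new, S)
      lp_old <- lp_truncnorm_sum(theta[, 1], mu_a_vec, sigma[["a"]],
                                 0, Inf) +
        lp_truncnorm_sum(theta[, 2], mu_z_vec, sigma[["z"]], 0, 1) +
        sum(-(mu[["a"]] - pr_a$mu_loc)^2 / (2 * pr_a$mu_scale^2)) +
        sum(-(mu[["z"]] - pr_z$mu_loc)^2 / (2 * pr_z$mu_scale^2)) +
        (-sigma[["a"]]^2 / (2 * pr_a$sd_scale^2)) +
        (-sigma[["z"]]^2 / (2 * pr_z$sd_scale^2))
      lp_new <- lp_truncnorm_sum(a_new, mu_a_vec_new, sig_a_new, 0, Inf) +
        lp_truncnorm_sum(z_new, mu_z_vec_new, sig_z_new, 0, 1) +
        sum(-(mu_a_new - pr_a$mu_loc)^2 / (2 * pr_a$mu_scale^2)) +
        sum(-(mu_z_new - pr_z$mu_loc)^2 / (2 * pr_z$mu_scale^2)) +
        (-sig_a_new^2 / (2 * pr_a$sd_scale^2)) +
        (-sig_z_new^2 / (2 * pr_z$sd_scale^2))
      # Jacobian: (S + #mu_a + 1) log c - (S + #mu_z + 1) log c
      logr <- lp_new - lp_old +
        (length(mu[["a"]]) - length(mu[["z"]])) * eps
      acc1 <- is.finite(logr) && log(runif(1)) < logr
      if (acc1) {
        theta[, 1] <- a_new; theta[, 2] <- z_new
        mu[["a"]] <- mu_a_new; mu[["z"]] <- mu_z_new
        sigma[["a"]] <- sig_a_new; sigma[["z"]] <- sig_z_new
      }
    } else acc1 <- FALSE
    if (adapting)
      step_scale_all <- step_scale_all *
        exp(gam * (as.numeric(acc1) - target_acc))

    ## 2d. cohort shift move: add delta to every t0 (and its group mean)
    ##     and rescale every v so each subject's mean RT is unchanged;
    ##     travels the t0/v ridge at the cohort level.
    delta <- step_shift_all * rnorm(1)
    k <- theta[, 1] * (1 - theta[, 2])
    mu_w <- k / theta[, 3]
    t0_new <- theta[, 4] + delta
    mu_t0_new <- mu[["t0"]] + delta
    pr_v <- priors[["v"]]; pr_t <- priors[["t0"]]
    if (all(t0_new >= 0) && all(mu_w - delta > 0) &&
        mu_t0_new > pr_t$lower && mu_t0_new < pr_t$upper) {
      v_new <- k / (mu_w - delta)
      # carry the v hyperparameters along by the average log change
      m_v <- mean(log(v_new) - log(theta[, 3]))
      mu_v_new <- mu[["v"]] * exp(m_v)
      sig_v_new <- sigma[["v"]] * exp(m_v)
      mu_v_vec <- if ("v" %in% free) mu[["v"]][gi] else rep(mu[["v"]], S)
      mu_v_vec_new <- if ("v" %in% free) mu_v_new[gi] else
        rep(mu_v_new, S)
      lp_old <- lp_truncnorm_sum(theta[, 3], mu_v_vec, sigma[["v"]],
                                 0, Inf) +
        lp_truncnorm_sum(theta[, 4], rep(mu[["t0"]], S), sigma[["t0"]],
                         0, Inf) +
        sum(-(mu[["v"]] - pr_v$mu_loc)^2 / (2 * pr_v$mu_scale^2)) +
        (-sigma[["v"]]^2 / (2 * pr_v$sd_scale^2)) +
        (-(mu[["t0"]] - pr_t$mu_loc)^2 / (2 * pr_t$mu_scale^2))
      lp_new <- lp_truncnorm_sum(v_new, mu_v_vec_new, sig_v_new,
                                 0, Inf) +
        lp_truncnorm_sum(t0_new, rep(mu_t0_new, S), sigma[["t0"]],
                         0, Inf) +
        sum(-(mu_v_new - pr_v$mu_loc)^2 / (2 * pr_v$mu_scale^2)) +
        (-sig_v_new^2 / (2 * pr_v$sd_scale^2)) +
        (-(mu_t0_new - pr_t$mu_loc)^2 / (2 * pr_t$mu_scale^2))
      theta_new <- cbind(theta[, 1], theta[, 2], v_new, t0_new)
      ll_new <- ll_fun(theta_new)
      logr <- sum(ll_new) - sum(ll) + lp_new - lp_old +
        2 * sum(log(v_new) - log(theta[, 3])) +
        (length(mu[["v"]]) + 1) * m_v
      acc1 <- all(mu_v_new > pr_v$lower) && all(mu_v_new < pr_v$upper) &&
        is.finite(logr) && log(runif(1)) < logr
      if (acc1) {
        theta[, 3] <- v_new; theta[, 4] <- t0_new
        mu[["t0"]] <- mu_t0_new
        mu[["v"]] <- mu_v_new; sigma[["v"]] <- sig_v_new
        ll <- ll_new
      }
    } else acc1 <- FALSE
    if (adapting)
      step_shift_all <- step_shift_all *
        exp(gam * (as.numeric(acc1) - target_acc))

    ## 2e. cohort moment-preserving move: common t0 shift delta for every
    ##     subject, each subject's (z, v) recomputed to keep that subject's
    ##     RT mean and variance, hyperparameters carried along.  This is
    ##     the cohort-level version of 2b2 and the main engine for mixing
    ##     over the weakly identified overall non-decision time; it is
    ##     cheap (one likelihood pass), so it is applied several times per
    ##     sweep to speed diffusion along the ridge.
    for (mpr_rep in 1:4) {
    k <- theta[, 1] * (1 - theta[, 2])
    mu_w <- k / theta[, 3]
    var_w <- mu_w / theta[, 3]^2
    delta <- step_mpr_all * rnorm(1)
    t0_new <- theta[, 4] + delta
    mu_new <- mu_w - delta
    mu_t0_new <- mu[["t0"]] + delta
    ok <- all(t0_new >= 0) && all(mu_new > 0) &&
      mu_t0_new > pr_t$lower && mu_t0_new < pr_t$upper
    if (ok) {
      v_new <- sqrt(mu_new / var_w)
      k_new <- mu_new * v_new
      z_new <- 1 - k_new / theta[, 1]
      ok <- all(z_new > 0) && all(z_new < 1)
    }
    if (ok) {
      m_v_all <- mean(log(v_new) - log(theta[, 3]))
      m_k_all <- mean(log(k_new) - log(k))
      if ("v" %in% free) {
        m_v_g <- vapply(seq_len(G), function(g)
          mean(log(v_new[gi == g]) - log(theta[gi == g, 3])), numeric(1))
      } else m_v_g <- m_v_all
      if ("z" %in% free) {
        m_k_g <- vapply(seq_len(G), function(g)
          mean(log(k_new[gi == g]) - log(k[gi == g])), numeric(1))
      } else m_k_g <- m_k_all
      mu_v_new <- mu[["v"]] * exp(m_v_g)
      sig_v_new <- sigma[["v"]] * exp(m_v_all)
      mu_z_new <- 1 - (1 - mu[["z"]]) * exp(m_k_g)
      sig_z_new <- sigma[["z"]] * exp(m_k_all)
      pr_z <- priors[["z"]]
      ok <- all(mu_v_new > pr_v$lower) && all(mu_v_new < pr_v$upper) &&
        all(mu_z_new > pr_z$lower) && all(mu_z_new < pr_z$upper)
    }
    if (ok) {
      theta_new <- cbind(theta[, 1], z_new, v_new, t0_new)
      ll_new <- ll_fun(theta_new)
      mu_z_vec <- if ("z" %in% free) mu[["z"]][gi] else rep(mu[["z"]], S)
      mu_v_vec <- if ("v" %in% free) mu[["v"]][gi] else rep(mu[["v"]], S)
      mu_z_vec_new <- if ("z" %in% free) mu_z_new[gi] else
        rep(mu_z_new, S)
      mu_v_vec_new <- if ("v" %in% free) mu_v_new[gi] else
        rep(mu_v_new, S)
      hyp <- function(muv, sig, prm) {
        sum(-(muv - prm$mu_loc)^2 / (2 * prm$mu_scale^2)) -
          sig^2 / (2 * prm$sd_scale^2)
      }
      lp_old <- lp_truncnorm_sum(theta[, 2], mu_z_vec, sigma[["z"]],
                                 0, 1) +
        lp_truncnorm_sum(theta[, 3], mu_v_vec, sigma[["v"]], 0, Inf) +
        lp_truncnorm_sum(theta[, 4], rep(mu[["t0"]], S), sigma[["t0"]],
                         0, Inf) +
        hyp(mu[["z"]], sigma[["z"]], priors[["z"]]) +
        hyp(mu[["v"]], sigma[["v"]], pr_v) +
        (-(mu[["t0"]] - pr_t$mu_loc)^2 / (2 * pr_t$mu_scale^2))
      lp_new <- lp_truncnorm_sum(z_new, mu_z_vec_new, sig_z_new, 0, 1) +
        lp_truncnorm_sum(v_new, mu_v_vec_new, sig_v_new, 0, Inf) +
        lp_truncnorm_sum(t0_new, rep(mu_t0_new, S), sigma[["t0"]],
                         0, Inf) +
        hyp(mu_z_new, sig_z_new, priors[["z"]]) +
        hyp(mu_v_new, sig_v_new, pr_v) +
        (-(mu_t0_new - pr_t$mu_loc)^2 / (2 * pr_t$mu_scale^2))
      logr <- sum(ll_new) - sum(ll) + lp_new - lp_old +
        sum(log(mu_new / mu_w)) +
        sum(m_v_g) + m_v_all + sum(m_k_g) + m_k_all
      acc1 <- is.finite(logr) && log(runif(1)) < logr
      if (acc1) {
        theta[, 2] <- z_new; theta[, 3] <- v_new; theta[, 4] <- t0_new
        mu[["z"]] <- mu_z_new; mu[["v"]] <- mu_v_new
        mu[["t0"]] <- mu_t0_new
        sigma[["z"]] <- sig_z_new; sigma[["v"]] <- sig_v_new
        ll <- ll_new
      }
    } else acc1 <- FALSE
    if (adapting)
      step_mpr_all <- step_mpr_all *
        exp(gam * (as.numeric(acc1) - target_acc))
    }

    ## 3. group-level means
    for (j in seq_along(PARAMS4)) {
      p <- PARAMS4[j]
      pr <- priors[[p]]
      dom <- param_domain(p)
      for (g in seq_along(mu[[p]])) {
        idx <- if (p %in% free) which(gi == g) else seq_len(S)
        x <- theta[idx, j]
        cur <- mu[[p]][g]
        prop <- cur + step_mu[[p]][g] * rnorm(1)
        if (prop <= pr$lower || prop >= pr$upper) {
          acc1 <- FALSE
        } else {
          lcur <- -(cur - pr$mu_loc)^2 / (2 * pr$mu_scale^2) +
            lp_truncnorm_sum(x, cur, sigma[[p]], dom[1], dom[2])
          lprop <- -(prop - pr$mu_loc)^2 / (2 * pr$mu_scale^2) +
            lp_truncnorm_sum(x, prop, sigma[[p]], dom[1], dom[2])
          acc1 <- is.finite(lprop) && log(runif(1)) < lprop - lcur
        }
        if (acc1) mu[[p]][g] <- prop
        if (adapting)
          step_mu[[p]][g] <- step_mu[[p]][g] *
            exp(gam * (as.numeric(acc1) - target_acc))
      }
    }

    ## 4. group-level SDs (shared across groups), log-scale random walk
    for (j in seq_along(PARAMS4)) {
      p <- PARAMS4[j]
      pr <- priors[[p]]
      dom <- param_domain(p)
      x <- theta[, j]
      mu_vec <- if (p %in% free) mu[[p]][gi] else rep(mu[[p]], S)
      cur <- sigma[[p]]
      prop <- cur * exp(step_sigma[[p]] * rnorm(1))
      lcur <- -cur^2 / (2 * pr$sd_scale^2) + log(cur) +
        lp_truncnorm_sum(x, mu_vec, cur, dom[1], dom[2])
      lprop <- -prop^2 / (2 * pr$sd_scale^2) + log(prop) +
        lp_truncnorm_sum(x, mu_vec, prop, dom[1], dom[2])
      acc1 <- is.finite(lprop) && log(runif(1)) < lprop - lcur
      if (acc1) sigma[[p]] <- prop
      if (adapting)
        step_sigma[[p]] <- step_sigma[[p]] *
          exp(gam * (as.numeric(acc1) - target_acc))
    }

    ## 5. record
    if (!adapting) {
      keep <- it - n_adapt
      draws[keep, ] <- c(unlist(mu), unlist(sigma), as.vector(t(theta)))
      deviance[keep] <- -2 * sum(ll)
    }
  }
  list(draws = draws, deviance = deviance)
}

## ---- public fitting interface -------------------------------------------

#' Fit a hierarchical one-choice drift-diffusion model
#'
#' Subject-level parameters follow truncated-normal population distributions
#' whose means are group-specific for the parameters freed by the
#' [model_spec()] and shared otherwise (between-subject SDs are always
#' shared).  The likelihood is the product over subjects of shifted-Wald
#' densities of their post-exclusion responded go RTs, in seconds; stop
#' trials do not enter the likelihood.  Sampling is adaptive random-walk
#' Metropolis-within-Gibbs on transformed scales (log for `a` and `v`, logit
#' for `z`, identity for `t0`), with proposal scales tuned only during a
#' preliminary adaptation phase.
#'
#' @param trials a trial table (ms); go trials are filtered through
#'   [exclusion_filter()] unless `filter = FALSE`.
#' @param spec a [model_spec()].
#' @param priors see [default_priors()].
#' @param config a [mcmc_config()].
#' @param filter apply the standard exclusion filter first.
#' @param rt_ceiling_ms right-truncation point of the likelihood in ms.
#'   Go trials slower than the exclusion cutoff are dropped before fitting,
#'   so the retained RTs follow the first-passage density truncated at the
#'   cutoff; each subject's likelihood is normalized by the first-passage
#'   mass below it.  Defaults to the exclusion cutoff (1250 ms) when
#'   `filter = TRUE`; set `NULL` for the plain untruncated density (which
#'   is negatively biased in `t0` whenever the cutoff clips the RT
#'   distribution's right tail).
#' @return object of class `hddm_fit`: post-burn-in `draws` (list of
#'   per-chain matrices), `deviance` traces, `dic`/`pd`, split-R-hat and
#'   effective sample sizes per parameter, group labels, the spec and
#'   config, and a `converged` flag (all R-hat < 1.1; a non-converged fit
#'   is flagged, never suppressed).
#' @export
fit_hddm <- function(trials, spec = model_spec(2), priors = default_priors(),
                     config = mcmc_config(), filter = TRUE,
                     rt_ceiling_ms = if (filter) 1250 else NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  if (filter) trials <- exclusion_filter(trials)
  go <- trials[trials$type == "go" & trials$responded & !is.na(trials$rt_ms),
               , drop = FALSE]
  if (nrow(go) == 0L) stop("no responded go trials after exclusion")
  subjects <- sort(unique(go$subject))
  S <- length(subjects)
  si <- match(go$subject, subjects)
  subj_group <- go$group[match(subjects, go$subject)]
  groups <- sort(unique(subj_group))
  G <- length(groups)
  gi <- match(subj_group, groups)
  free <- spec$free_by_group
  if (length(free) > 0 && G < 2)
    stop("group-varying parameters require at least two group labels")
  rt <- go$rt_ms / 1000
  min_rt <- vapply(split(rt, si), min, numeric(1))
  if (any(min_rt <= 0))
    stop("subject(s) ", paste(subjects[min_rt <= 0], collapse = ", "),
         " have minimum RT <= 0 ms, inconsistent with any non-negative ",
         "non-decision time")

  ceiling_s <- if (is.null(rt_ceiling_ms)) NULL else rt_ceiling_ms / 1000
  ntr <- as.vector(table(factor(si, levels = seq_len(S))))
  chains <- lapply(seq_len(config$n_chains), function(ch)
    run_chain(rt, si, S, gi, G, free, priors, config,
              chain_seed = config$seed + ch - 1L,
              ceiling = ceiling_s, ntr = ntr))

  post <- (config$burn_in + 1L):config$n_samples
  draws <- lapply(chains, function(c_) c_$draws[post, , drop = FALSE])
  deviance <- lapply(chains, function(c_) c_$deviance[post])

  # rename group-indexed and subject-indexed columns with real labels
  cn <- colnames(draws[[1]])
  for (g in seq_len(G))
    cn <- gsub(sprintf("\\[g%d\\]", g), sprintf("[%s]", groups[g]), cn)
  for (s in seq_len(S)) {
    cn <- gsub(sprintf("^(a|z|v|t0)\\[%d\\]$", s),
               sprintf("\\1[%s]", subjects[s]), cn)
  }
  draws <- lapply(draws, function(d) { colnames(d) <- cn; d })

  # Deviance at the posterior mean: the likelihood sees a subject only
  # through the identified shifted-Wald coordinates, and the posterior can
  # travel a curved, weakly identified ridge trading t0 against the Wald
  # mean and shape.  Averaging each raw parameter separately can therefore
  # land OFF the ridge and give a meaningless plug-in deviance; averaging
  # the predicted moments (mean RT, RT variance) together with t0 and
  # reconstructing (k, v) from them keeps the plug-in point on the ridge.
  all_draws <- do.call(rbind, draws)
  a_cols <- paste0("a[", subjects, "]")
  z_cols <- paste0("z[", subjects, "]")
  v_cols <- paste0("v[", subjects, "]")
  t_cols <- paste0("t0[", subjects, "]")
  k_dr <- all_draws[, a_cols, drop = FALSE] *
    (1 - all_draws[, z_cols, drop = FALSE])
  v_dr <- all_draws[, v_cols, drop = FALSE]
  t_dr <- all_draws[, t_cols, drop = FALSE]
  mu_dr <- k_dr / v_dr                    # Wald mean
  m_bar <- colMeans(mu_dr + t_dr)         # predicted mean RT
  w_bar <- exp(colMeans(log(mu_dr / v_dr^2)))  # predicted RT variance
  t_bar <- colMeans(t_dr)
  mu_bar <- m_bar - t_bar
  v_bar <- sqrt(mu_bar / w_bar)
  k_bar <- mu_bar * v_bar
  # any (a, z) with a (1 - z) = k_bar gives the same deviance
  theta_bar <- cbind(2 * k_bar, 0.5, v_bar, t_bar)
  dev_at_mean <- -2 * sum(ll_by_subject(theta_bar, rt, si, S,
                                        ceiling_s, ntr))
  dic_stats <- dic(unlist(deviance), dev_at_mean)

  rhat <- apply_diag(draws, split_rhat)
  ess <- apply_diag(draws, function(m) sum(apply(m, 2, ess_one)))
  fit <- structure(list(
    draws = draws, deviance = deviance, dev_at_mean = dev_at_mean,
    dic = dic_stats[["DIC"]], pd = dic_stats[["pD"]],
    rhat = rhat, ess = ess,
    converged = all(rhat[is.finite(rhat)] < 1.1),
    spec = spec, priors = priors, config = config,
    rt_ceiling_ms = rt_ceiling_ms,
    groups = groups, subjects = subjects,
    n_go_trials = nrow(go), n_draws = length(post) * config$n_chains),
    class = "hddm_fit")
  fit
}

# apply a per-parameter diagnostic across the list of chain matrices
apply_diag <- function(draws, f) {
  cn <- colnames(draws[[1]])
  vapply(cn, function(nm) {
    m <- sapply(draws, function(d) d[, nm])
    f(as.matrix(m))
  }, numeric(1))
}

#' @export
print.hddm_fit <- function(x, ...) {
  free <- if (length(x$spec$free_by_group))
    paste(x$spec$free_by_group, collapse = ", ") else "none"
  cat(sprintf(
    "hierarchical one-choice DDM fit (model %s; group-varying: %s)\n",
    x$spec$id, free))
  cat(sprintf("  %d subjects, %d go trials, %d retained draws\n",
              length(x$subjects), x$n_go_trials, x$n_draws))
  cat(sprintf("  DIC = %.1f (pD = %.1f); max split-R-hat = %.3f%s\n",
              x$dic, x$pd, max(x$rhat[is.finite(x$rhat)]),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Deviance information criterion from a deviance trace
#'
#' `pD` is the posterior-mean deviance minus the deviance at the posterior
#' mean (the Spiegelhalter effective parameter count);
#' `DIC = mean deviance + pD`.
#'
#' @param deviance either an `hddm_fit` (whose stored trace is used) or a
#'   numeric vector of post-burn-in deviance draws.
#' @param deviance_at_mean the deviance evaluated at the posterior means
#'   (required for a numeric trace).
#' @return named numeric vector `c(DIC, pD)`.
#' @export
dic <- function(deviance, deviance_at_mean = NULL) {
  if (inherits(deviance, "hddm_fit")) {
    if (!is.null(deviance_at_mean))
      stop("deviance_at_mean is taken from the fit")
    return(dic(unlist(deviance$deviance), deviance$dev_at_mean))
  }
  stopifnot(is.numeric(deviance), length(deviance) >= 2,
            is.numeric(deviance_at_mean))
  bad <- which(!is.finite(deviance))
  if (length(bad))
    stop("non-finite deviance draw(s) at position(s) ",
         paste(head(bad, 5), collapse = ", "))
  dbar <- mean(deviance)
  pd <- dbar - deviance_at_mean
  c(DIC = dbar + pd, pD = pd)
}

#' Posterior proportion for a group contrast
#'
#' The fraction of post-burn-in draws in which the group-level mean of
#' `parameter` is larger in `group_a` than in `group_b`.
#'
#' @param fit an `hddm_fit`.
#' @param parameter one of the fit's group-varying parameters.
#' @param group_a,group_b group labels present in the fit.
#' @return proportion in \[0, 1\].
#' @export
posterior_proportion <- function(fit, parameter, group_a, group_b) {
  stopifnot(inherits(fit, "hddm_fit"))
  if (!parameter %in% fit$spec$free_by_group)
    stop("'", parameter, "' is not group-varying in the fitted model")
  if (!all(c(group_a, group_b) %in% fit$groups))
    stop("unknown group label(s)")
  ca <- sprintf("mu_%s[%s]", parameter, group_a)
  cb <- sprintf("mu_%s[%s]", parameter, group_b)
  all_draws <- do.call(rbind, fit$draws)
  mean(all_draws[, ca] > all_draws[, cb])
}

#' Extract posterior draws as one matrix
#'
#' @param fit an `hddm_fit`.
#' @param pars optional regular expression selecting parameter columns.
#' @return matrix of post-burn-in draws, chains stacked.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "hddm_fit"))
  m <- do.call(rbind, fit$draws)
  if (!is.null(pars)) m <- m[, grepl(pars, colnames(m)), drop = FALSE]
  m
}
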