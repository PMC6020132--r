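#' Temporal estimation error
#'
#' TEE is the response time minus the collision time; responses with
#' `tee <= 0` ms are classified as early (the boundary is inclusive:
#' a response exactly at the collision counts as early).
#'
#' @param rt_ms vector of response times in ms.
#' @param collision_time collision time in ms.
#' @return data.frame with columns `tee` (ms) and `sign`
#'   (`"early"`/`"late"`).
#' @examples
#' compute_tee(c(898.84, 1000, 1100))
#' @export
compute_tee <- function(rt_ms, collision_time = 1000) {
  stopifnot(is.numeric(rt_ms), length(collision_time) == 1L)
  tee <- rt_ms - collision_time
  data.frame(tee = tee,
             sign = ifelse(tee <= 0, "early", "late"),
             stringsAsFactors = FALSE)
}

#' Exclude implausible go trials
#'
#' Drops go trials with `rt_ms > max_rt_ms` (too slow) or
#' `rt_ms < min_rt_ms` (anticipations); both inequalities are strict, so a
#' trial at exactly the cutoff is retained.  Stop trials pass through
#' untouched.  The input is never modified; counts and proportions per group
#' are attached as the attribute `"exclusion_log"`.  The filter is
#' idempotent.
#'
#' @param trials a trial table.
#' @param max_rt_ms upper go-RT cutoff in ms (default 1250).
#' @param min_rt_ms lower go-RT cutoff in ms (default 0).
#' @return the filtered trial table.
#' @export
exclusion_filter <- function(trials, max_rt_ms = 1250, min_rt_ms = 0) {
  go <- trials$type == "go"
  slow <- go & !is.na(trials$rt_ms) & trials$rt_ms > max_rt_ms
  fast <- go & !is.na(trials$rt_ms) & trials$rt_ms < min_rt_ms
  drop <- slow | fast
  log <- do.call(rbind, lapply(split(seq_len(nrow(trials)), trials$group),
    function(i) {
      n_go <- sum(go[i])
      data.frame(n_go = n_go, n_slow = sum(slow[i]), n_fast = sum(fast[i]),
                 prop_slow = if (n_go) sum(slow[i]) / n_go else 0,
                 prop_fast = if (n_go) sum(fast[i]) / n_go else 0)
    }))
  log <- cbind(group = rownames(log), log)
  rownames(log) <- NULL
  out <- trials[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- log
  attr(out, "subjects") <- attr(trials, "subjects")
  out
}

#' Two-sample t statistic from group summaries
#'
#' Welch or pooled-variance two-sample t computed from group means, SDs and
#' sizes.  The statistic and degrees of freedom are reported; p-values are
#' deliberately not (the pipeline reports effect direction and magnitude
#' only).
#'
#' @param m1,sd1,n1 first group mean, SD, size (`n1 >= 2`).
#' @param m2,sd2,n2 second group mean, SD, size.
#' @param variant `"welch"` (unequal variances, Welch-Satterthwaite df) or
#'   `"pooled"` (classical, df `n1 + n2 - 2`).
#' @return list of class `summary_t`: `statistic`, `df`, `variant`, and the
#'   summaries used.
#' @examples
#' two_sample_t(66.53, 4.07, 15, 50.60, 8.52, 15, "welch")
#' @export
two_sample_t <- function(m1, sd1, n1, m2, sd2, n2,
                         variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (m1 != m2)
      stop("zero variance in both groups with unequal means: ",
           "t statistic undefined")
    stat <- 0
    df <- n1 + n2 - 2
  } else if (variant == "welch") {
    se1 <- sd1^2 / n1; se2 <- sd2^2 / n2
    stat <- (m1 - m2) / sqrt(se1 + se2)
    df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  structure(list(statistic = stat, df = df, variant = variant,
                 summaries = data.frame(mean = c(m1, m2), sd = c(sd1, sd2),
                                        n = c(n1, n2))),
            class = "summary_t")
}

#' @export
print.summary_t <- function(x, ...) {
  cat(sprintf("two-sample t (%s): t(%.2f) = %.2f\n",
              x$variant, x$df, x$statistic))
  invisible(x)
}

#' Paired t statistic on subject means
#'
#' Thin wrapper around [stats::t.test()] with `paired = TRUE`; used for the
#' within-subject comparison of signal-respond versus go response times
#' (df = n - 1 over subject means).
#'
#' @param x,y paired vectors of subject means.
#' @return list of class `summary_t` with `statistic`, `df`,
#'   `variant = "paired"`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 variant = "paired",
                 summaries = data.frame(mean = c(mean(x), mean(y)),
                                        sd = c(sd(x), sd(y)),
                                        n = c(length(x), length(y)))),
            class = "summary_t")
}

#' Group-level summary table
#'
#' Mean and SD per group of the study's summary measures: absolute TEE,
#' go RT, signal-respond RT and inhibition accuracy are computed over
#' trials; SSD50 and mean-method SSRT over per-subject values (matching the
#' subject-level regressions they feed).  Expects an already-filtered trial
#' table (see [exclusion_filter()]).
#'
#' @param trials a filtered trial table.
#' @param collision_time collision time in ms.
#' @return data.frame with columns `group`, `measure`, `mean`, `sd`, `n`,
#'   `level` (`"trial"` or `"subject"`).  Inhibition accuracy is in percent.
#' @export
group_summary <- function(trials, collision_time = 1000) {
  groups <- unique(trials$group)
  out <- list()
  for (g in groups) {
    tg <- trials[trials$group == g, , drop = FALSE]
    if (length(unique(tg$subject)) == 0L) {
      warning("group '", g, "' has no subjects; omitted")
      next
    }
    go_rt <- tg$rt_ms[tg$type == "go" & tg$responded]
    sr_rt <- tg$rt_ms[tg$outcome == "signal-respond"]
    abs_tee <- abs(compute_tee(go_rt, collision_time)$tee)
    inhib <- 100 * (tg$outcome[tg$type == "stop"] == "signal-stop")
    rs <- race_summary(tg, collision_time = collision_time, filter = FALSE)
    row <- function(measure, x, level) {
      data.frame(group = g, measure = measure, mean = mean(x),
                 sd = if (length(x) > 1) sd(x) else 0, n = length(x),
                 level = level, stringsAsFactors = FALSE)
    }
    out[[g]] <- rbind(
      row("abs_tee_ms", abs_tee, "trial"),
      row("rt_go_ms", go_rt, "trial"),
      row("rt_signal_respond_ms", sr_rt, "trial"),
      row("inhibition_accuracy_pct", inhib, "trial"),
      row("ssd50_ms", rs$ssd50[!is.na(rs$ssd50)], "subject"),
      row("ssrt_ms", rs$ssrt[!is.na(rs$ssrt)], "subject")
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
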