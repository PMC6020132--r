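#' SSD50: the tracked 50%-response stop-signal delay
#'
#' Under the symmetric 1-up/1-down staircase the presented SSDs oscillate
#' around the delay at which the subject responds on half of the stop
#' trials; SSD50 is estimated as the arithmetic mean of the presented SSDs
#' over the subject's experimental stop trials.  An alternative estimator,
#' the mean of the staircase reversal points, is available via `method`.
#'
#' @param stop_trials the stop-trial rows of one subject (trial table
#'   subset), in presentation order.
#' @param method `"presented"` (default) or `"reversal"`.
#' @return SSD50 in ms, or `NA` if there are no stop trials (with a
#'   warning).
#' @export
ssd50 <- function(stop_trials, method = c("presented", "reversal")) {
  method <- match.arg(method)
  ssds <- stop_trials$ssd_ms[stop_trials$type == "stop"]
  if (length(ssds) == 0L) {
    warning("no stop trials; SSD50 is NA")
    return(NA_real_)
  }
  if (method == "presented") return(mean(ssds))
  resp <- stop_trials$responded[stop_trials$type == "stop"]
  rev_pts <- ssds[c(FALSE, diff(resp) != 0)]
  if (length(rev_pts) == 0L) return(mean(ssds))
  mean(rev_pts)
}

#' Mean-method stop-signal reaction time
#'
#' The mean method estimates the latency of the covert stop process as the
#' subject's mean go response time minus the tracked SSD50.
#'
#' @param mean_rt_go mean go RT in ms (vectorized).
#' @param ssd50 tracked SSD50 in ms.
#' @return SSRT in ms.
#' @examples
#' ssrt_mean_method(898.84, 590.14)   # 308.70
#' ssrt_mean_method(1004.51, 728.67)  # 275.84
#' @export
ssrt_mean_method <- function(mean_rt_go, ssd50) {
  stopifnot(is.numeric(mean_rt_go), is.numeric(ssd50))
  mean_rt_go - ssd50
}

#' Inhibition accuracy
#'
#' Fraction of a subject's stop trials on which the response was withheld
#' (outcome signal-stop).
#'
#' @inheritParams ssd50
#' @return proportion in \[0, 1\].
#' @export
inhibition_accuracy <- function(stop_trials) {
  st <- stop_trials[stop_trials$type == "stop", , drop = FALSE]
  if (nrow(st) == 0L) stop("no stop trials")
  mean(st$outcome == "signal-stop")
}

#' Adjusted Fisher-Pearson skewness
#'
#' The standardized third moment with the small-sample adjustment
#' `sqrt(n (n - 1)) / (n - 2)`.
#'
#' @param x numeric vector, length at least 3.
#' @return dimensionless skewness.
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Context-independence check of the race model
#'
#' The independent horse-race model implies that signal-respond responses
#' are the fast tail of the go distribution, hence
#' mean RT(signal-respond) < mean RT(go).  Reports both means, their
#' difference and the direction flag for one subject.
#'
#' @param trials trial-table rows of one subject.
#' @return list: `mean_rt_go`, `mean_rt_signal_respond`, `difference`
#'   (go minus signal-respond), `signal_respond_faster` flag, trial counts.
#'   Missing inputs give `NA` fields with a warning.
#' @export
context_independence_check <- function(trials) {
  go_rt <- trials$rt_ms[trials$type == "go" & trials$responded]
  sr_rt <- trials$rt_ms[trials$outcome == "signal-respond"]
  if (length(go_rt) == 0L || length(sr_rt) == 0L) {
    warning("need at least one responded go trial and one signal-respond ",
            "trial; returning NA")
    return(list(mean_rt_go = NA_real_, mean_rt_signal_respond = NA_real_,
                difference = NA_real_, signal_respond_faster = NA,
                n_go = length(go_rt), n_signal_respond = length(sr_rt)))
  }
  mg <- mean(go_rt); ms <- mean(sr_rt)
  list(mean_rt_go = mg, mean_rt_signal_respond = ms,
       difference = mg - ms, signal_respond_faster = ms < mg,
       n_go = length(go_rt), n_signal_respond = length(sr_rt))
}

#' Per-subject race-model summary table
#'
#' For every subject: post-exclusion mean go RT, mean signal-respond RT,
#' SSD50, mean-method SSRT, inhibition accuracy, go-RT skewness, the
#' per-subject OLS slope of go RT on trial number (the drift-over-trials
#' reliability check for the mean method), and trial counts.
#'
#' @param trials a trial table (all subjects).
#' @param collision_time collision time in ms (unused in the summary itself,
#'   kept for interface symmetry with [group_summary()]).
#' @param filter apply [exclusion_filter()] first (default `TRUE`); the mean
#'   go RT entering the SSRT estimate is always the post-exclusion mean.
#' @param ssd50_method passed to [ssd50()].
#' @return data.frame of class `race_summary`, one row per subject:
#'   `subject`, `group`, `mean_rt_go`, `mean_rt_signal_respond`, `ssd50`,
#'   `ssrt`, `inhibition_accuracy`, `skewness_rt_go`, `rt_trend_slope`,
#'   `n_go_used`, `n_stop`.
#' @export
race_summary <- function(trials, collision_time = 1000, filter = TRUE,
                         ssd50_method = "presented") {
  if (filter) trials <- exclusion_filter(trials)
  out <- lapply(split(trials, trials$subject), function(ts) {
    go <- ts[ts$type == "go" & ts$responded, , drop = FALSE]
    st <- ts[ts$type == "stop", , drop = FALSE]
    s50 <- if (nrow(st)) ssd50(st, method = ssd50_method) else NA_real_
    mg <- if (nrow(go)) mean(go$rt_ms) else NA_real_
    sr <- ts$rt_ms[ts$outcome == "signal-respond"]
    slope <- if (nrow(go) >= 3L)
      unname(coef(lm(rt_ms ~ trial, data = go))[2]) else NA_real_
    data.frame(
      subject = ts$subject[1], group = ts$group[1],
      mean_rt_go = mg,
      mean_rt_signal_respond = if (length(sr)) mean(sr) else NA_real_,
      ssd50 = s50,
      ssrt = ssrt_mean_method(mg, s50),
      inhibition_accuracy = if (nrow(st)) inhibition_accuracy(st) else
        NA_real_,
      skewness_rt_go = skewness(go$rt_ms),
      rt_trend_slope = slope,
      n_go_used = nrow(go), n_stop = nrow(st),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("race_summary", "data.frame")
  res
}
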