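#' Group-level generating distributions for a synthetic cohort
#'
#' Describes one group of subjects: truncated-normal between-subject
#' distributions for the diffusion parameters (`a`, `z`, `v`, `t0`, units as
#' in [ddm_params()]) and the trial-level stop-process latency distribution
#' (`ssrt_mean`, `ssrt_sd`, milliseconds, truncated at 0).
#'
#' @param label group name (unique within a cohort).
#' @param n_subjects number of subjects, at least 1.
#' @param a_mean,a_sd threshold mean and between-subject SD.
#' @param z_mean,z_sd relative starting point mean and SD.
#' @param v_mean,v_sd drift-rate mean and SD.
#' @param t0_mean,t0_sd non-decision time mean and SD (seconds).
#' @param ssrt_mean,ssrt_sd stop-signal reaction time mean and trial-level SD
#'   in milliseconds.
#' @return an object of class `group_spec`.
#' @seealso [default_group_specs()] for the package's reference two-group
#'   cohort.
#' @export
group_spec <- function(label, n_subjects,
                       a_mean, a_sd, z_mean, z_sd,
                       v_mean, v_sd, t0_mean, t0_sd,
                       ssrt_mean, ssrt_sd) {
  stopifnot(is.character(label), nchar(label) > 0, n_subjects >= 1)
  sds <- c(a_sd, z_sd, v_sd, t0_sd, ssrt_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all SDs must be finite and >= 0")
  if (a_mean <= 0 || v_mean <= 0) stop("a_mean and v_mean must be > 0")
  if (z_mean <= 0 || z_mean >= 1) stop("z_mean must lie in (0, 1)")
  if (t0_mean < 0) stop("t0_mean must be >= 0")
  if (ssrt_mean <= 0) stop("ssrt_mean must be > 0 (milliseconds)")
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 a_mean = a_mean, a_sd = a_sd,
                 z_mean = z_mean, z_sd = z_sd,
                 v_mean = v_mean, v_sd = v_sd,
                 t0_mean = t0_mean, t0_sd = t0_sd,
                 ssrt_mean = ssrt_mean, ssrt_sd = ssrt_sd),
            class = "group_spec")
}

#' Reference two-group cohort specification
#'
#' The package's default synthetic cohort: two groups of 15 subjects whose
#' generating parameters follow the published summary table of the
#' schizophrenia time-to-collision stop-signal study this package models —
#' the group difference is concentrated in the starting point `z`
#' (0.43 vs 0.30, between-subject SD 0.12) while threshold (8.86), drift
#' (8.48, between-subject SD 0.2) and non-decision time (0.28 s) are shared.
#' The published parameter dispersions are posterior uncertainties of
#' group-level means, not between-subject SDs (the non-decision dispersion,
#' 0.91 s, exceeds its 0.28 s mean, impossible for a non-negative
#' parameter), so the generator chooses between-subject SDs once, calibrated
#' to the study's printed observables: per-group subject-mean go-RT SDs of
#' 134 ms (patients) and 30 ms (controls), and only a small percentage of
#' go trials beyond the 1250 ms exclusion cutoff.  This gives a starting
#' point SD of 0.10 for the patient-like group and 0.02 for the control-like
#' group, with `a` SD 0.2, `v` SD 0.2 and `t0` SD 0.02 s shared; see the
#' methods vignette.  Group stop latencies use the published mean-method
#' SSRT summaries (308.7 ms SD 76.38; 275.84 ms SD 55.26) as the
#' trial-level stop-process distribution.
#'
#' @return a named list of two [group_spec()] objects, `sz` and `control`.
#' @export
default_group_specs <- function() {
  list(
    sz = group_spec("SZ", 15,
                    a_mean = 8.86, a_sd = 0.2,
                    z_mean = 0.43, z_sd = 0.10,
                    v_mean = 8.48, v_sd = 0.2,
                    t0_mean = 0.28, t0_sd = 0.02,
                    ssrt_mean = 308.7, ssrt_sd = 76.38),
    control = group_spec("control", 15,
                         a_mean = 8.86, a_sd = 0.2,
                         z_mean = 0.30, z_sd = 0.02,
                         v_mean = 8.48, v_sd = 0.2,
                         t0_mean = 0.28, t0_sd = 0.02,
                         ssrt_mean = 275.84, ssrt_sd = 55.26)
  )
}

#' Session (task) configuration
#'
#' The task timeline in milliseconds: five experimental blocks of 30 go and
#' 10 stop trials by default, a ball-collision at 1000 ms after motion onset,
#' a 2700 ms response window, and a 1-up/1-down staircase moving the
#' stop-signal delay by 30 ms after every stop trial.
#'
#' @param n_blocks number of experimental blocks.
#' @param go_per_block,stop_per_block trials per block by type.
#' @param staircase_step staircase step in ms (`> 0`; a zero step is allowed
#'   and freezes the SSD, useful for fixed-delay simulations).
#' @param initial_ssd starting stop-signal delay in ms.
#' @param ssd_bounds length-2 vector, SSD clamp interval in ms.
#' @param collision_time collision time in ms (TEE reference point).
#' @param response_deadline end of the response window in ms.
#' @param seed integer master seed for cohort simulation.
#' @return an object of class `session_config`.
#' @export
session_config <- function(n_blocks = 5, go_per_block = 30,
                           stop_per_block = 10, staircase_step = 30,
                           initial_ssd = 500, ssd_bounds = c(30, 2400),
                           collision_time = 1000, response_deadline = 2700,
                           seed = 1L) {
  stopifnot(n_blocks >= 1, go_per_block >= 0, stop_per_block >= 0,
            staircase_step >= 0, length(ssd_bounds) == 2L)
  if (!(collision_time > 0 && collision_time < response_deadline))
    stop("need 0 < collision_time < response_deadline")
  if (ssd_bounds[1] <= 0 || ssd_bounds[2] >= response_deadline ||
      ssd_bounds[1] > ssd_bounds[2])
    stop("ssd_bounds must be an interval within (0, response_deadline)")
  if (initial_ssd < ssd_bounds[1] || initial_ssd > ssd_bounds[2])
    stop("initial_ssd must lie within ssd_bounds")
  structure(list(n_blocks = as.integer(n_blocks),
                 go_per_block = as.integer(go_per_block),
                 stop_per_block = as.integer(stop_per_block),
                 staircase_step = staircase_step,
                 initial_ssd = initial_ssd, ssd_bounds = ssd_bounds,
                 collision_time = collision_time,
                 response_deadline = response_deadline,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Draw one subject's parameters from a group specification
#'
#' Subject-level diffusion parameters are drawn from normal distributions
#' truncated to each parameter's domain (`a > 0`, `0 < z < 1`, `v > 0`,
#' `t0 >= 0`); the subject inherits the group's trial-level stop-latency
#' distribution.
#'
#' @param spec a [group_spec()] object.
#' @param seed optional integer seed (private stream).
#' @return a list of class `stop_subject` with elements `params`
#'   (a [ddm_params()]), `ssrt_mean`, `ssrt_sd` (ms) and `group`.
#' @export
draw_subject <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "group_spec"))
  doms <- list(a = c(0, Inf), z = c(0, 1), v = c(0, Inf), t0 = c(0, Inf))
  for (p in names(doms)) {
    m <- spec[[paste0(p, "_mean")]]; s <- spec[[paste0(p, "_sd")]]
    if (truncnorm_mass(m, s, doms[[p]][1], doms[[p]][2]) < 1e-6)
      stop(sprintf(
        "group '%s': less than 1e-6 of the '%s' distribution lies in its domain",
        spec$label, p))
  }
  with_seed(seed, {
    a  <- rtruncnorm(1, spec$a_mean, spec$a_sd, 0, Inf)
    z  <- rtruncnorm(1, spec$z_mean, spec$z_sd, 0, 1)
    v  <- rtruncnorm(1, spec$v_mean, spec$v_sd, 0, Inf)
    t0 <- rtruncnorm(1, spec$t0_mean, spec$t0_sd, 0, Inf)
    structure(list(params = ddm_params(a, z, v, t0),
                   ssrt_mean = spec$ssrt_mean, ssrt_sd = spec$ssrt_sd,
                   group = spec$label),
              class = "stop_subject")
  })
}

# draw one trial-level SSRT (ms) for a subject; truncated normal at 0
draw_ssrt <- function(subject) {
  rtruncnorm(1, subject$ssrt_mean, subject$ssrt_sd, 0, Inf)
}

#' Simulate one stop trial under the independent horse-race model
#'
#' Draws a go-process finishing time from the subject's diffusion and a stop
#' latency (SSRT) from the subject's truncated-normal stop process,
#' independently.  The response is inhibited (signal-stop) iff
#' `rt_go > ssd + ssrt`, strictly; a tie counts as signal-respond.  The same
#' go-process stream is used whether or not a stop signal occurs, so context
#' independence holds by construction.
#'
#' @param subject a `stop_subject` (see [draw_subject()]).
#' @param ssd stop-signal delay in ms.
#' @return one-row data.frame with `ssd_ms`, `responded`, `rt_ms` (`NA` when
#'   inhibited), `outcome` (`"signal-respond"` or `"signal-stop"`), and the
#'   latent `ssrt_ms`.
#' @export
simulate_stop_trial <- function(subject, ssd) {
  stopifnot(inherits(subject, "stop_subject"), ssd >= 0)
  rt_go <- 1000 * ddm_sample(subject$params, 1)  # ms
  ssrt <- draw_ssrt(subject)
  inhibited <- rt_go > ssd + ssrt
  data.frame(ssd_ms = ssd,
             responded = !inhibited,
             rt_ms = if (inhibited) NA_real_ else rt_go,
             outcome = if (inhibited) "signal-stop" else "signal-respond",
             ssrt_ms = ssrt,
             stringsAsFactors = FALSE)
}

#' Simulate a full session for one subject
#'
#' `n_blocks` blocks of `go_per_block` go and `stop_per_block` stop trials;
#' stop trials occupy uniformly random positions within each block.  The
#' staircase raises the SSD by `staircase_step` after each signal-stop and
#' lowers it after each signal-respond, clamped to `ssd_bounds`, and is
#' carried across blocks.  Go-trial response times may exceed the response
#' deadline; nothing is dropped here — exclusion is a downstream, logged step.
#'
#' @param subject a `stop_subject`.
#' @param config a [session_config()].
#' @return data.frame with one row per trial: `block`, `trial` (within
#'   session), `type`, `ssd_ms`, `responded`, `rt_ms`, `outcome`.
#' @export
simulate_session <- function(subject, config) {
  stopifnot(inherits(subject, "stop_subject"),
            inherits(config, "session_config"))
  per_block <- config$go_per_block + config$stop_per_block
  n_total <- config$n_blocks * per_block
  block <- integer(n_total); type <- character(n_total)
  ssd_col <- rep(NA_real_, n_total); responded <- logical(n_total)
  rt <- rep(NA_real_, n_total); outcome <- character(n_total)

  ssd <- config$initial_ssd
  row <- 0L
  for (b in seq_len(config$n_blocks)) {
    stop_pos <- sort(sample.int(per_block, config$stop_per_block))
    for (j in seq_len(per_block)) {
      row <- row + 1L
      block[row] <- b
      if (j %in% stop_pos) {
        tr <- simulate_stop_trial(subject, ssd)
        type[row] <- "stop"; ssd_col[row] <- ssd
        responded[row] <- tr$responded; rt[row] <- tr$rt_ms
        outcome[row] <- tr$outcome
        step <- if (tr$outcome == "signal-stop") config$staircase_step else
          -config$staircase_step
        ssd <- min(max(ssd + step, config$ssd_bounds[1]),
                   config$ssd_bounds[2])
      } else {
        type[row] <- "go"
        rt[row] <- 1000 * ddm_sample(subject$params, 1)
        responded[row] <- TRUE
        outcome[row] <- "go"
      }
    }
  }
  data.frame(block = block, trial = seq_len(n_total), type = type,
             ssd_ms = ssd_col, responded = responded, rt_ms = rt,
             outcome = outcome, stringsAsFactors = FALSE)
}

#' Simulate a multi-group cohort
#'
#' Draws each group's subjects from its [group_spec()] and simulates one
#' session per subject.  Fully reproducible from the specs and the seed in
#' `config`.
#'
#' @param specs list of [group_spec()] objects with unique labels.
#' @param config a [session_config()]; its `seed` drives all randomness.
#' @return a trial table: data.frame with columns `subject`, `group`,
#'   `block`, `trial`, `type`, `ssd_ms`, `responded`, `rt_ms`, `outcome`.
#'   The drawn subject parameters are attached as attribute `"subjects"`.
#' @export
simulate_cohort <- function(specs, config = session_config()) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "group_spec")))
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate group labels: ",
                                  paste(labels[duplicated(labels)],
                                        collapse = ", "))
  with_seed(config$seed, {
    out <- vector("list", sum(vapply(specs, `[[`, integer(1), "n_subjects")))
    subjects <- list()
    k <- 0L
    for (spec in specs) {
      for (i in seq_len(spec$n_subjects)) {
        k <- k + 1L
        id <- sprintf("%s%02d", spec$label, i)
        subj <- draw_subject(spec)
        ses <- simulate_session(subj, config)
        out[[k]] <- cbind(data.frame(subject = id, group = spec$label,
                                     stringsAsFactors = FALSE), ses)
        subjects[[id]] <- subj
      }
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    attr(tab, "subjects") <- subjects
    tab
  })
}

#' Run a pure staircase sequence of consecutive stop trials
#'
#' Simulates `n_trials` consecutive stop trials for one subject under the
#' 1-up/1-down staircase, with no interleaved go trials.  Used to study the
#' convergence of the tracking procedure: for any subject whose response
#' probability is continuous and increasing in SSD, the long-run proportion
#' of signal-respond trials converges to 50%.
#'
#' @param subject a `stop_subject`.
#' @param n_trials number of stop trials.
#' @param initial_ssd,step,bounds staircase geometry in ms.
#' @param seed optional integer seed (private stream).
#' @return data.frame with `trial`, `ssd_ms`, `responded`, `outcome`.
#' @export
staircase_run <- function(subject, n_trials, initial_ssd = 500, step = 30,
                          bounds = c(30, 2400), seed = NULL) {
  stopifnot(inherits(subject, "stop_subject"), n_trials >= 1)
  with_seed(seed, {
    # vectorized draws; staircase update is the only sequential part
    rt_go <- 1000 * ddm_sample(subject$params, n_trials)
    ssrt <- rtruncnorm(n_trials, subject$ssrt_mean, subject$ssrt_sd, 0, Inf)
    ssd <- numeric(n_trials)
    responded <- logical(n_trials)
    cur <- initial_ssd
    for (i in seq_len(n_trials)) {
      ssd[i] <- cur
      responded[i] <- rt_go[i] <= cur + ssrt[i]
      cur <- cur + if (responded[i]) -step else step
      cur <- min(max(cur, bounds[1]), bounds[2])
    }
    data.frame(trial = seq_len(n_trials), ssd_ms = ssd,
               responded = responded,
               outcome = ifelse(responded, "signal-respond", "signal-stop"),
               stringsAsFactors = FALSE)
  })
}
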