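# Fixtures shared across test files.  Everything is generated in code.

table1_params <- function() ddm_params(a = 8.86, z = 0.43, v = 8.48,
                                       t0 = 0.28)

# a subject with a degenerate (zero-variance) go and stop process, for
# deterministic race-rule checks
degenerate_subject <- function(rt_go_ms = 900, ssrt_ms = 300) {
  spec <- group_spec("deg", 1,
                     a_mean = 8.86, a_sd = 0,
                     z_mean = 0.43, z_sd = 0,
                     v_mean = 8.48, v_sd = 0,
                     t0_mean = 0.28, t0_sd = 0,
                     ssrt_mean = ssrt_ms, ssrt_sd = 0)
  s <- draw_subject(spec, seed = 1)
  # overwrite the diffusion with an effectively deterministic go process:
  # huge threshold distance and drift give vanishing Wald variance around
  # the target decision time
  target <- rt_go_ms / 1000 - 0.0
  s$params <- ddm_params(a = 4000, z = 0.5, v = 2000 / target, t0 = 0)
  s
}

# small two-group specification for fast fits (z-only group difference of
# 0.13 by default, matching the reference cohort's structure)
small_specs <- function(n = 10, z_sz = 0.43) {
  list(
    group_spec("SZ", n, a_mean = 8.86, a_sd = 0.2,
               z_mean = z_sz, z_sd = 0.10, v_mean = 8.48, v_sd = 0.2,
               t0_mean = 0.28, t0_sd = 0.02,
               ssrt_mean = 308.7, ssrt_sd = 76.38),
    group_spec("control", n, a_mean = 8.86, a_sd = 0.2,
               z_mean = 0.30, z_sd = 0.02, v_mean = 8.48, v_sd = 0.2,
               t0_mean = 0.28, t0_sd = 0.02,
               ssrt_mean = 275.84, ssrt_sd = 55.26)
  )
}

# trial table for a handful of subjects built directly (no simulator), for
# exact-arithmetic checks of the race/behavioral statistics
toy_trials <- function() {
  rbind(
    data.frame(subject = "s1", group = "g", block = 1L, trial = 1:3,
               type = "go", ssd_ms = NA_real_, responded = TRUE,
               rt_ms = c(900, 1000, 1100), outcome = "go",
               stringsAsFactors = FALSE),
    data.frame(subject = "s1", group = "g", block = 1L, trial = 4:5,
               type = "stop", ssd_ms = c(470, 530), responded = TRUE,
               rt_ms = c(850, 950), outcome = "signal-respond",
               stringsAsFactors = FALSE),
    data.frame(subject = "s1", group = "g", block = 1L, trial = 6L,
               type = "stop", ssd_ms = 500, responded = FALSE,
               rt_ms = NA_real_, outcome = "signal-stop",
               stringsAsFactors = FALSE)
  )
}
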