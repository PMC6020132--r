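---
title: "Modelling go/stop temporal prediction with stopwald"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling go/stop temporal prediction with stopwald}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopwald)
```

# The task and the models

`stopwald` analyses a time-to-collision stop-signal experiment.  On a *go
trial* a ball moves for 1000 ms towards a collision with a second ball, and
the subject presses a key at the predicted collision moment; the signed
difference between response time and collision time is the temporal
estimation error (TEE), with `TEE <= 0` classified as *early*.  On a *stop
trial* the display turns red after a stop-signal delay (SSD) and the subject
must withhold the prepared response.  A 1-up/1-down staircase raises the SSD
30 ms after every successful stop and lowers it 30 ms after every failure,
so the presented SSDs track the delay at which the subject responds on half
the stop trials (SSD50).  A session is five blocks of 30 go and 10 stop
trials.

Two models give this task its quantitative content.

**The independent horse race.**  A go process with finishing time
`RT_go` and a stop process with latency SSRT race independently; the
response is inhibited iff `RT_go > SSD + SSRT` (a tie counts as a
response).  The *mean method* estimates the stop latency as
`SSRT = mean(RT_go) - SSD50`.  Context independence — the assumption that
the go finishing-time distribution is the same with and without a stop
signal — implies that signal-respond RTs are the fast tail of the go
distribution, hence faster on average.

**The one-choice drift-diffusion model.**  Evidence accumulates with drift
`v` from a starting point `z·a` towards a single threshold `a` (diffusion
coefficient fixed at 1, the package's only scaling convention; `z` is a
dimensionless fraction).  The decision time is then Wald (inverse-Gaussian)
distributed with mean `mu = a(1 - z)/v` and shape `lambda = (a(1 - z))^2`,
and the observed RT adds a non-decision time `t0`:

$$ f(t) = \sqrt{\frac{\lambda}{2\pi (t - t_0)^3}}
   \exp\left\{-\frac{\lambda\,[(t - t_0) - \mu]^2}{2\mu^2 (t - t_0)}\right\},
   \qquad t > t_0. $$

In the precision framing that motivates the study, `z` indexes the
confidence placed in prior beliefs (a higher starting point shortens the
distance to threshold and produces premature responses), `v` indexes
sensory precision, and `a` strategic response caution.  Four hierarchical
variants encode competing explanations of a group difference in go RT:
model 1 frees the group means of `z` and `v`, model 2 only `z`, model 3
only `v`, model 4 only `a`; `t0` is always shared.  No inter-trial
variability parameters are estimated.  Sampling from the Wald uses the
Michael–Schucany–Haas transformation (exact, rejection-free).

# The synthetic cohort

Because no subject-level data are deposited with the study, the package is
exercised end to end on synthetic cohorts whose generating conditions come
from the published summary table: two groups of 15 subjects, group
starting-point means 0.43 (patient-like) and 0.30 (control-like), shared
threshold 8.86, drift 8.48 and non-decision time 0.28 s, and a collision at
1000 ms inside a 2700 ms response window.

The published parameter dispersions are posterior uncertainties of
group-level means, not between-subject spreads: the printed non-decision
dispersion (0.91 s) exceeds its mean (0.28 s), which is impossible for a
non-negative parameter.  The generator's between-subject SDs are therefore
the package's own choice, calibrated once against the study's printed
*observables*: per-group subject-mean go-RT SDs of roughly 134 ms
(patients) and 30 ms (controls), and a slow-trial exclusion rate of a few
percent.  The defaults are a starting-point SD of 0.10 (patient-like) and
0.02 (control-like) with threshold SD 0.2, drift SD 0.2 and non-decision SD
0.02 s shared.  Two consequences are worth noting: the fitted hierarchy
assumes a shared starting-point SD, so the generator is deliberately
allowed to be mildly misspecified in that respect; and the calibration was
frozen before the recovery analyses below were interpreted.

The stop process is a truncated normal (at zero) over trial-level SSRTs,
parameterized per group by the published mean-method SSRT summaries
(308.7 ms, SD 76.38; 275.84 ms, SD 55.26).  The study treats SSRT purely
phenomenologically, so the simulator's choice of a trial-level (rather than
subject-level) stop distribution is a modelling convention, documented here
and pluggable through `group_spec()`.  The staircase is carried continuously
across blocks (the study does not say whether it was reset; a continuous
track is the natural reading of an adaptive procedure), starts at 500 ms —
between the two groups' published SSD50 values — and is clamped to
[30, 2400] ms.  Stop trials occupy uniformly random positions within each
block.  Go RTs beyond the response deadline are recorded, never silently
dropped; exclusion is a separate, logged step.  The simulator cannot
produce the anticipatory `RT < 0 ms` responses real subjects make (1.6% in
the study) because the pure diffusion process starts at motion onset; the
exclusion filter still handles them on ingested data.

What passing tests on this cohort do *not* show: real RT distributions
carry lapses, anticipations and left-skewed components (the study observed
left-skewed go RTs, whereas a pure shifted Wald is right-skewed by
construction — the package asserts this property explicitly); recovery on
the synthetic cohort demonstrates the pipeline's internal consistency, not
the adequacy of the one-choice model for any particular dataset.

# Exclusion and the truncated likelihood

Go trials with `RT > 1250` ms or `RT < 0` ms are excluded before analysis
(both inequalities strict, so a trial at exactly 1250 ms is retained).  The
hierarchical likelihood is the product over subjects of shifted-Wald
densities of the retained go RTs — *right-truncated at the exclusion
ceiling*, i.e. normalized per subject by the first-passage mass below
1250 ms.  The truncation correction matters more than it looks: the shift
parameter `t0` is identified largely by the distribution's third moment,
and dropping even 1–2% of the right tail removes enough skewness that the
plain density systematically under-estimates `t0` (profile analyses on
synthetic cohorts place the plain-density optimum 0.1 s below the
generating value, dragging the absolute starting points with it).  With the
truncated likelihood the generating group starting points are recovered
within a few hundredths.  Setting `rt_ceiling_ms = NULL` in `fit_hddm()`
restores the uncorrected density for comparison.

# Priors, sampler and numerical choices

Priors (the study states none) are weakly informative at the scale the
summary table implies, and every entry is overridable: group means
`a ~ N(5, 5^2)` on (0, ∞), `z ~ N(0.5, 0.25^2)` on (0, 1),
`v ~ N(5, 5^2)` on (0, ∞), `t0 ~ N(0.3, 0.3^2)` s on (0, ∞);
between-subject SDs half-normal with scale 1 (0.2 for `z`).  Shared
between-subject SDs across groups; only the group means named by the model
variant differ (a sensitivity toggle the study leaves open).

The sampler is an adaptive random-walk Metropolis-within-Gibbs scheme
written for this likelihood's geometry.  One-choice data identify a subject
only through `k = a(1 - z)`, `v` and `t0`; two near-flat ridges result:
`(a, z)` at fixed `k` (purely prior-identified) and the
moment-preserving direction that trades `t0` against the Wald mean and
shape.  Component-wise proposals mix glacially along these ridges, so each
sweep adds dedicated moves with exact Jacobians:

* per-subject and cohort-level *scale moves* that rescale `a` (and its
  hyperparameters) while adjusting `z` to keep every `k` fixed — the
  likelihood is untouched by construction;
* per-subject and cohort-level *moment-preserving moves* that shift `t0`
  and recompute `(z, v)` so each subject's predicted RT mean and variance
  are unchanged (in `(mean, variance, t0)` coordinates this is a unit-Jacobian
  shear; the `(z, v)` chart contributes `mu/var^2`);
* a `t0`–`v` trade holding `k` and the mean fixed.

Proposal scales adapt by Robbins–Monro towards ~30% acceptance only during
a preliminary adaptation phase (default 500 sweeps, discarded), so the
short burn-in applied to the retained draws (default 200 of 10,000, the
study's settings) is honest.  Subject parameters are proposed on log
(`a`, `v`), logit (`z`) and identity (`t0`) scales; subjects are updated in
a single vectorized pass per parameter.  Initialization is
method-of-moments with a cohort-common `t0` start (a per-subject start
correlates with group and can seed a spurious group split along the weakly
identified `t0` direction); chains are over-dispersed by small jitters.
Default 4 chains for split-R-hat and effective-sample-size diagnostics,
which are always reported; a fit with any split-R-hat above 1.1 is flagged,
never suppressed.

DIC uses the Spiegelhalter effective parameter count,
`pD = mean(D) - D(posterior mean)` with `D = -2` × go-trial log-likelihood.
The plug-in point is computed from posterior means of each subject's
*identified moment coordinates* (predicted mean RT, predicted RT variance,
`t0`), reconstructing `(k, v)` from them: averaging raw parameters
separately can land off the curved ridge and produce meaningless (large
negative) `pD`.  Any `(a, z)` pair with the right product gives the same
deviance.

# What model comparison can and cannot decide here

Because only `k = a(1 - z)` enters the likelihood, a group difference in
the starting point (model 2) and one in the threshold (model 4) are
*likelihood-equivalent* accounts of any group difference in `k`; model 1
nests model 2 at about one extra effective parameter, and only model 3 (a
drift difference) is weakly distinguishable, through the Wald's
mean–variance coupling.  On synthetic cohorts with a pure starting-point
difference the four DICs accordingly land within a few units of one
another, and the "winner" is decided by Monte-Carlo noise between models 2
and 4.  This is a property of the model family and data, not of the
sampler; it is worth keeping in mind when interpreting decisive published
DIC margins between these variants.  The group *contrast itself* is robust:
the posterior proportion of draws with the patient-like starting point
above the control-like one exceeds 0.95 whenever the generating difference
is present, under every model that frees `z`.

The study's three mixed-effects regressions are deliberately replaced by
two-stage statistics (subject means, then Welch/pooled/paired t) — the
random-effects machinery is off-the-shelf and adds nothing to what the
pipeline demonstrates; the aggregate report labels the substitution.
p-values are not reproduced; the pipeline reports statistics and degrees of
freedom.

# Problem sizes

The recovery analyses in the test suite run at the study's scale — 15 + 15
subjects with 150 go and 50 stop trials each — with 2 chains of 1,500
adaptation plus 3,500 retained sweeps for the parameter-recovery fit, and
ten replicates of scaled-down cohorts (10 + 10 subjects, three blocks,
single chains of 600 + 1,200 sweeps) for model recovery; these sizes give
Monte-Carlo errors comfortably below every tolerance asserted and keep a
full run of the suite inexpensive.  Staircase and likelihood checks use
10^4–10^6 draws.

# Known limitations

* Absolute `t0` (and with it the absolute level of `z`) is weakly
  identified at 150 trials per subject; the posterior along the
  moment-preserving ridge has an SD of several tens of milliseconds, and
  group contrasts are far better determined than absolute levels.
* DIC cannot separate starting-point from threshold accounts in one-choice
  data (see above).
* The generator emulates a stationary subject; fatigue and strategy drift
  (the study's RT-on-trial reliability regressions) exist in the pipeline
  only as the per-subject OLS trend check.
* The integration method for SSRT is not implemented (the study names it
  as future work); only the mean method is.
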