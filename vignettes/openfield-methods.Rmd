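---
title: "Methods: peri-event open-field analysis and its simulated ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-event open-field analysis and its simulated ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openfieldr)
library(dplyr)
```

# The measurement problem

Brief optogenetic activation of dorsal raphe serotonin neurons transiently
suppresses locomotion in the open field, while repeated daily stimulation
slowly *increases* baseline speed across weeks. Quantifying both effects from
centroid tracking raises four methodological problems this package addresses:

1. **Peri-event speed estimation.** Speed must be computed from noisy
   tracking, smoothed without blurring a sub-second onset, and averaged in
   fixed windows around each stimulation train.
2. **Mean reversion.** Conditioning post-stimulation speed on prior speed
   creates regression toward the mean even in unstimulated data; the effect
   of stimulation conditioned on prior speed is only interpretable after
   subtracting a sham estimate of that reversion.
3. **Place preference vs. slowing.** When stimulation is delivered only
   inside a region of interest (ROI), increased ROI occupancy is ambiguous:
   it can reflect learned place value or a pure in-ROI slowing. Entry and
   exit rates dissociate the two.
4. **Slow drift across sessions.** A per-session facilitation of baseline
   speed in stimulated animals is estimated by ordinary least squares of
   pre-stimulation speed on session, group, and their interaction.

# Protocol and windows

The standard session is 30 min of alternating 5-min blocks, always starting
unstimulated; within each stimulated block a 3-s train is delivered every
10 s. Under these defaults `make_schedule()` yields 90 trains and exactly
270 s of stimulation per session:

```{r protocol}
pro <- stim_protocol()
total_stim_time(pro)
```

Two pulse-rate presets reflect the two variants in common use, 25 Hz
(`"short_term"`) and 20 Hz (`"long_term"`); the discrepancy is retained as a
pair of presets rather than resolved. At 20 Hz the 5,400 pulses per session
amount to `r round(100 * pulse_budget_fraction(stim_protocol(preset = "long_term")), 2)`%
of the 86,400 spikes a 1 Hz neuron fires per day — the spike-budget argument
that daily sessions perturb total serotonergic activity only modestly.

`make_sham_schedule()` places events at the *identical within-block phase*
in the unstimulated blocks. "Equivalent times in non-stimulated blocks" is
the least-assumption reading, and phase-matching makes real and sham events
exchangeable under the null — the property the mean-reversion correction
relies on.

Speed at frame $i$ is the centroid displacement from frame $i-1$ times the
frame rate, smoothed by a five-frame running median (boundary frames use a
shrunken symmetric window; the first frame and frames following a flagged
tracking gap are masked, never interpolated — dropouts are not described by
upstream trackers well enough to interpolate safely). The analysis windows
are half-open intervals relative to train onset: pre $[-2, 0)$ s and post
$[+1, +3)$ s, the post window skipping the first second of the ~1 s
suppression onset. Events whose windows leave the session, cross a block
boundary, or touch a masked gap are dropped and counted.

# The sham-corrected quartile conditioning

For one mouse, quartile cut points are computed from the pre-speeds of that
mouse's *real* events by linear interpolation between order statistics
(type-7 quantiles; the rule is pinned because several conventions exist).
Sham events are binned by the same cuts so that real and sham bins cover
identical speed ranges. Within each quartile the mean delta speed
(post − pre) is computed separately for real and sham events and subtracted:

$$\mathrm{dod}_q = \overline{\Delta v}^{\,\mathrm{real}}_q - \overline{\Delta v}^{\,\mathrm{sham}}_q .$$

Raw per-quartile deltas show strong regression toward the mean (positive in
the slowest quartile, negative in the fastest) even with no stimulation at
all; the subtraction cancels it exactly under the null because the sham
events experience the same conditional reversion. The delta-of-delta is also
invariant to adding any constant to all speeds, so additive drift within a
session cannot masquerade as an effect. Sham deltas are subtracted
mouse-by-mouse (not at the cohort level); cohort statistics are unweighted
means across mice with SEM, matching the per-animal averaging convention
used throughout.

# ROI conditioning metrics

The closed-loop assay defines a 13 × 10.5 cm rectangle centered in the
arena; stimulation is on exactly while the centroid is inside. The three
session metrics are ROI occupancy, entry rate = entries / time outside, and
exit rate = exits / time inside. A *pure slowing* effect (lower speed inside
the ROI, no attraction) raises occupancy and lowers the exit rate while
leaving the entry rate unchanged, because behavior outside the ROI — which
alone determines entries per unit outside time — is untouched. A learned
place preference would instead raise the entry rate. Visits are maximal
runs of inside frames with half-open boundary membership; no minimum-dwell
debounce is applied by default (stimulation terminates immediately on exit),
but a `debounce_s` parameter exists for noisy tracking.

# Long-term regression

`fit_longterm()` estimates, by OLS,

$$v_{\mathrm{pre}} = \beta_0 + \beta_1\,\mathrm{session} + \beta_2\,\mathrm{group} + \beta_3\,(\mathrm{session} \times \mathrm{group}),$$

with session 1-based and uncentered and group coded 1 for the
stimulated-from-day-1 group (G1) and 0 for the delayed group (G2), so
$\beta_3$ is the excess per-session slope attributable to repeated
stimulation. Mice are pooled (the design's regression is plain OLS; a
mixed-effects variant is a possible extension, not implemented). Two
confound-avoiding checks relate day-to-day fluctuations of the transient
effect to the slow drift: procedure A regresses
$v_{\mathrm{pre}}(n{+}1) - v_{\mathrm{pre}}(n{-}1)$ on $\Delta v(n)$;
procedure B first detrends each mouse's $v_{\mathrm{pre}}$ linearly against
session and regresses the residual at $n+1$ on $\Delta v(n)$. Both pool
mouse-session pairs by default (`pool = FALSE` gives per-mouse fits), report
$R^2$, the slope and a two-sided p-value, and count their own pairs rather
than forcing any particular exclusion bookkeeping. All tests in the package
are two-sided; the two-sample t test uses pooled variance.

# The simulator

`simulate_session()` is the package's ground truth: the simplest stochastic
process exhibiting every feature the analyses measure. It is explicitly
*not* a model of mouse locomotion.

- **Speed**: a mean-reverting (Ornstein–Uhlenbeck) target speed $v$ with
  mean `mu_v`, reversion rate `theta_per_s` and noise `sigma_v`, clamped at
  zero, Euler-discretized at `1/fps`.
- **Behavioral states**: a Markov chain over walking, rearing, resting,
  grooming, digging with per-second leave rates and destination weights;
  each state multiplies the target speed (resting/grooming ≈ 0). The
  emitted ethogram is the true state path.
- **Heading**: diffusive with persistence time `kappa_s`, steered toward the
  nearest wall at rate `w_wall` (thigmotaxis), reflected at walls.
- **Stimulation**: a multiplicative gain relaxing toward `g_stim` with time
  constant `tau_on_s` (0.5 s) during trains and back to 1 with `tau_off_s`
  (1.5 s) after — reproducing a >90% onset within ~1 s — plus an optional
  multiplier on mobile-to-resting transition rates (`rest_boost`), the
  state-probability counterpart of the transient effect. Both are
  independently switchable; `freq_scaling` makes the gain proportional to
  pulse rate for dose-response studies.
- **Long-term drift**: `drift_lambda` is added to `mu_v` once per stimulated
  session already experienced, so drift persists regardless of same-day
  stimulation; G2 stays flat until its stimulation start.
- **ROI mode**: stimulation is on exactly while the centroid is inside the
  rectangle and *no attraction or repulsion toward the ROI is ever
  injected*, making the simulated animal place-value-free by construction.

Defaults are chosen to match the study regime: a 50 × 40 cm arena tracked
at 60 frames/s; `mu_v = 11.5` cm/s so that with the default state occupancy
the measured pre-window speed is ≈ 6 cm/s, the observed open-field baseline;
`g_stim = 0.5`, matching the observed roughly-halving of speed. The per-frame
dynamics run in compiled code and draw from R's RNG, so a seed fully
determines every emitted file.

What the simulator does **not** emulate: body orientation and gait, tracking
dropout patterns, arena-edge rearing artifacts, inter-mouse variability in
thigmotaxis, and any learning. Passing tests therefore certify the
*analysis* logic — window bookkeeping, the reversion correction, the rate
definitions, the regression — not the realism of any movement model.

# Calibration and recovery checks

The acceptance suite ties the analysis and the simulator together at sizes
chosen to keep the full run in minutes (all sizes are package choices,
stated here):

- **Reversion correction**: 20 replicate 70-min sessions (≈ 210 trains each,
  30 frames/s). With the gain off, the corrected per-quartile effect is null
  (each |mean| < 2 SEM) while raw sham deltas show reversion; with gain 0.5
  the corrected effect grows monotonically across quartiles.
- **ROI dissociation**: 20 ten-minute sessions per condition; occupancy and
  exit rate shift under in-ROI slowing (two-sample tests, α = 0.05), entry
  rate does not, and all metrics return to baseline in an unstimulated
  post condition.
- **Drift recovery**: cohorts of 3+3 mice × 10 sessions (10-min sessions,
  walking-only state model) with λ = 0.15 cm/s per session; the fitted
  $\beta_3$ covers λ at binomial-consistent rates over 20 cohorts, and λ = 0
  cohorts cover zero at the nominal 95% rate over 100 seeds. The recovery
  check uses the walking-only configuration deliberately: with mixed states
  the measured pre-speed slope is λ times the mean state multiplier — an
  uninteresting nuisance factor — whereas with a single mobile state the
  injected λ is, by construction, the true regression slope.
- **Null calibration**: with all effects off, the per-session paired
  pre/post comparison rejects at 5% ± binomial error over 200 sessions.

Numerical conventions collected in one place: half-open intervals
everywhere (windows, zones, ROI membership, quartile bins via
`(c_{q-1}, c_q]`); zone boundaries lower/left inclusive; type-7 quantiles;
speed assigned to the frame ending each displacement; first frame masked;
shrunken symmetric median windows at series boundaries; rates with zero
denominators reported as `NA` and flagged rather than dropped silently.

# Worked example

```{r example}
cfg <- sim_config(fps = 30)           # study-like conditions, lighter frame rate
pro <- stim_protocol()
s <- simulate_session(cfg, protocol = pro, seed = 1)
speed <- compute_speed(s$track)
ew <- event_windows(speed, s$events, block_len_s = pro$block_len_s)
mouse_delta(ew)

sham <- event_windows(speed, make_sham_schedule(pro), block_len_s = pro$block_len_s)
quartile_conditioning(ew, sham)
```

The per-quartile `dod` column is the sham-corrected effect; under the
default gain of 0.5 it grows in magnitude from the slowest to the fastest
quartile, the signature of multiplicative suppression.

# Known limitations

- The movement model's stationary speed distribution is approximately
  truncated-normal per state; real open-field speed distributions are
  heavier-tailed, so absolute histogram shapes should not be over-read.
- OLS pooling of mice understates uncertainty when mice differ strongly in
  baseline; the cohort helpers average per-mouse statistics first for that
  reason, but `fit_longterm()` itself is plain OLS by design.
- The entry/exit rate dissociation assumes the tracker does not jitter
  across the ROI boundary; with real tracking enable `debounce_s`.
- File validation reports the first offending line; it does not attempt
  repair.
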