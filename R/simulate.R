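#' Behavioral state model for the simulator
#'
#' States switch as a discrete-time approximation of a Markov jump process:
#' each state is left at `leave_rate` per second and the destination is
#' drawn from `dest_weight` (renormalized over the other states). Each state
#' scales the mean-reverting target speed by `mult` (resting and grooming
#' are immobile).
#'
#' @param names state names (subset of the ethogram vocabulary).
#' @param mult speed multiplier per state.
#' @param leave_rate per-second rate of leaving each state.
#' @param dest_weight relative destination weights.
#' @return `state_model` list with the per-second transition rate matrix.
#' @export
state_model <- function(names = c("walking", "rearing", "resting", "grooming", "digging"),
                        mult = c(1, 0.3, 0, 0, 0.15),
                        leave_rate = c(0.15, 0.4, 0.25, 0.3, 0.4),
                        dest_weight = c(0.45, 0.15, 0.2, 0.1, 0.1)) {
  k <- length(names)
  stopifnot(length(mult) == k, length(leave_rate) == k, length(dest_weight) == k)
  rates <- matrix(0, k, k, dimnames = list(names, names))
  if (k > 1) {
    for (s in seq_len(k)) {
      w <- dest_weight
      w[s] <- 0
      rates[s, ] <- leave_rate[s] * w / sum(w)
    }
  }
  structure(list(names = names, mult = mult, rates = rates,
                 is_mobile = names %in% MOBILE_STATES,
                 rest_state = match("resting", names)),
            class = "state_model")
}

#' @rdname state_model
#' @export
state_model_walking_only <- function() {
  state_model(names = "walking", mult = 1, leave_rate = 0, dest_weight = 1)
}

#' Simulator configuration
#'
#' The movement model is a state-switched mean-reverting (OU) speed process
#' driving a persistent-heading random walk with wall attraction and wall
#' reflection — the simplest process exhibiting every statistical feature
#' the analyses measure (it is not a model of real mouse locomotion).
#' Stimulation acts in two independently switchable ways: a multiplicative
#' gain on the target speed relaxing toward `g_stim` with time constant
#' `tau_on_s` during trains (and back to 1 with `tau_off_s` after), and a
#' `rest_boost` multiplier on the mobile-to-resting transition rate while
#' stimulation is on.
#'
#' @param arena_w,arena_h arena dimensions, cm.
#' @param fps frames per second.
#' @param mu_v baseline mean of the OU target speed, cm/s.
#' @param theta_per_s OU mean-reversion rate, 1/s.
#' @param sigma_v OU noise scale, cm/s per sqrt(s).
#' @param kappa_s heading persistence time, s (heading diffusion sd per step
#'   is `sqrt(dt / kappa_s)`).
#' @param w_wall wall-attraction steering rate, rad/s (0 = none).
#' @param states a [state_model()].
#' @param g_stim multiplicative speed gain under stimulation, in `[0, 1]`
#'   (1 = no effect).
#' @param tau_on_s,tau_off_s gain onset/offset time constants, s.
#' @param rest_boost stimulation multiplier on mobile-to-resting transition
#'   rates (1 = no effect).
#' @param freq_scaling if `TRUE`, the gain target for an event at `f` Hz is
#'   `1 - (1 - g_stim) * f / freq_ref_hz` (clamped at 0): suppression
#'   proportional to pulse rate.
#' @param freq_ref_hz reference frequency for `freq_scaling`.
#' @param drift_lambda per-session additive increment of `mu_v` for each
#'   stimulated session already experienced (long-term facilitation), cm/s.
#' @return `sim_config` list.
#' @export
sim_config <- function(arena_w = 50, arena_h = 40, fps = 60,
                       mu_v = 11.5, theta_per_s = 0.5, sigma_v = 2.5,
                       kappa_s = 2, w_wall = 0.5,
                       states = state_model(),
                       g_stim = 0.5, tau_on_s = 0.5, tau_off_s = 1.5,
                       rest_boost = 2, freq_scaling = FALSE, freq_ref_hz = 25,
                       drift_lambda = 0.15) {
  if (g_stim < 0 || g_stim > 1) abort("g_stim must lie in [0, 1]")
  if (fps <= 0) abort("fps must be positive")
  stopifnot(inherits(states, "state_model"))
  structure(list(arena_w = arena_w, arena_h = arena_h, fps = fps,
                 mu_v = mu_v, theta_per_s = theta_per_s, sigma_v = sigma_v,
                 kappa_s = kappa_s, w_wall = w_wall, states = states,
                 g_stim = g_stim, tau_on_s = tau_on_s, tau_off_s = tau_off_s,
                 rest_boost = rest_boost, freq_scaling = freq_scaling,
                 freq_ref_hz = freq_ref_hz, drift_lambda = drift_lambda),
            class = "sim_config")
}

gain_target_for <- function(cfg, pulse_hz) {
  if (!cfg$freq_scaling) return(rep(cfg$g_stim, length(pulse_hz)))
  pmax(0, 1 - (1 - cfg$g_stim) * pulse_hz / cfg$freq_ref_hz)
}

run_core <- function(cfg, n, stim_on, gain_target, roi = NULL, mu_v = cfg$mu_v) {
  sm <- cfg$states
  k <- length(sm$names)
  x0 <- stats::runif(1, 0.1 * cfg$arena_w, 0.9 * cfg$arena_w)
  y0 <- stats::runif(1, 0.1 * cfg$arena_h, 0.9 * cfg$arena_h)
  heading0 <- stats::runif(1, -pi, pi)
  state0 <- if (k > 1) sample.int(k, 1) else 1L
  .sim_core(n, 1 / cfg$fps, cfg$arena_w, cfg$arena_h,
            mu_v, cfg$theta_per_s, cfg$sigma_v,
            cfg$kappa_s, cfg$w_wall,
            sm$mult, sm$rates, sm$is_mobile,
            if (is.na(sm$rest_state)) -1L else sm$rest_state - 1L,
            cfg$tau_on_s, cfg$tau_off_s, cfg$rest_boost,
            stim_on, gain_target,
            !is.null(roi),
            roi$x0 %||% 0, roi$y0 %||% 0, roi$w %||% 0, roi$h %||% 0,
            cfg$g_stim,
            x0, y0, heading0, mu_v, state0 - 1L)
}

core_to_session <- function(cfg, res, n, mu_v) {
  tt <- (seq_len(n) - 1) / cfg$fps
  track <- as_tracking(tibble(frame = seq_len(n) - 1L, t = tt,
                              x = res$x, y = res$y),
                       fps = cfg$fps, arena_w = cfg$arena_w, arena_h = cfg$arena_h)
  st <- cfg$states$names[res$state]
  r <- rle(st)
  ends <- cumsum(r$lengths)
  ethogram <- tibble(onset_s = tt[ends - r$lengths + 1L],
                     offset_s = c(tt[ends[-length(ends)] + 1L],
                                  tt[n] + 1 / cfg$fps),
                     state = r$values)
  truth <- list(mu_v = mu_v, g_stim = cfg$g_stim,
                state = tibble(t = tt, state = st, v_true = res$v_true,
                               gain = res$gain, stim_on = res$stim_on))
  list(track = track, ethogram = ethogram, truth = truth)
}

#' Simulate one open-field session
#'
#' Generates a tracking series, an ethogram (the true state path), and the
#' events actually delivered, under a train schedule. With `schedule = NULL`
#' the default block/train protocol of [stim_protocol()] is used. Identical
#' seed and configuration give identical output.
#'
#' @param cfg a [sim_config()].
#' @param schedule events tibble (real events drive stimulation); `NULL` for
#'   the default protocol schedule.
#' @param protocol protocol used when `schedule` is `NULL` and to size the
#'   session.
#' @param session_len_s session length, s; default from `protocol`.
#' @param seed RNG seed (integer) or `NULL` to continue the current RNG
#'   stream.
#' @param mu_v override of the baseline mean speed (used by
#'   [simulate_cohort()] to inject drift).
#' @return `of_session` list: `track`, `events`, `ethogram`, `truth`.
#' @export
simulate_session <- function(cfg = sim_config(), schedule = NULL,
                             protocol = stim_protocol(),
                             session_len_s = NULL, seed = NULL,
                             mu_v = cfg$mu_v) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- make_schedule(protocol)
  session_len_s <- session_len_s %||% protocol$session_len_s
  n <- as.integer(round(session_len_s * cfg$fps))
  tt <- (seq_len(n) - 1) / cfg$fps
  stim_on <- rep(FALSE, n)
  gain_target <- rep(1, n)
  real <- filter(schedule, .data$kind == "real")
  if (nrow(real) > 0) {
    gt <- gain_target_for(cfg, real$pulse_hz)
    for (i in seq_len(nrow(real))) {
      sel <- tt >= real$onset_s[i] & tt < real$onset_s[i] + real$duration_s[i]
      stim_on[sel] <- TRUE
      gain_target[sel] <- gt[i]
    }
  }
  res <- run_core(cfg, n, stim_on, gain_target, mu_v = mu_v)
  out <- core_to_session(cfg, res, n, mu_v)
  structure(list(track = out$track, events = schedule,
                 ethogram = out$ethogram, truth = out$truth),
            class = "of_session")
}

#' Simulate a closed-loop ROI session
#'
#' Stimulation is on exactly while the centroid is inside the ROI; the
#' multiplicative gain applies as in [simulate_session()]. No attraction or
#' repulsion toward the ROI is ever injected, so the simulated animal is
#' place-value-free by construction: any occupancy change is a pure
#' consequence of slowing. The emitted events are the ROI visit intervals
#' (one continuous train per visit, 25 Hz, 20 mW).
#'
#' @param cfg a [sim_config()] (`g_stim = 1` for a no-effect session).
#' @param roi a [roi_rect()].
#' @param session_len_s session length, s.
#' @param seed RNG seed or `NULL`.
#' @return `of_session` list: `track`, `events`, `ethogram`, `truth`.
#' @export
simulate_roi_session <- function(cfg = sim_config(), roi = roi_rect(),
                                 session_len_s = 1800, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(session_len_s * cfg$fps))
  res <- run_core(cfg, n, logical(n), rep(1, n), roi = roi)
  out <- core_to_session(cfg, res, n, cfg$mu_v)
  # the event log is the closed-loop trigger record: one continuous train per
  # ROI visit, so event intervals equal roi_visits() intervals by construction
  v <- roi_visits(out$track, roi)
  events <- tibble(
    onset_s = v$entry_t,
    duration_s = v$exit_t - v$entry_t,
    pulse_hz = 25, pulse_width_ms = 10, amplitude_mw = 20,
    kind = "real", block_idx = NA_real_
  )
  structure(list(track = out$track, events = events,
                 ethogram = out$ethogram, truth = out$truth),
            class = "of_session")
}

#' Cohort design for long-term simulation
#'
#' Two groups of mice: G1 stimulated from session 1, G2 from session
#' `g2_stim_start` (so `g2_stim_start > n_sessions` gives a never-stimulated
#' control group over the simulated range).
#'
#' @param n_g1,n_g2 number of mice per group.
#' @param n_sessions sessions per mouse.
#' @param g2_stim_start first stimulated session for G2.
#' @param genotype genotype label for all simulated mice.
#' @return design tibble `mouse_id`, `genotype`, `group`, `stim_from` with
#'   attribute `n_sessions`.
#' @export
cohort_design <- function(n_g1 = 3, n_g2 = 3, n_sessions = 24,
                          g2_stim_start = 24, genotype = "SERT-Cre") {
  design <- tibble(
    mouse_id = c(sprintf("g1_m%02d", seq_len(n_g1)),
                 sprintf("g2_m%02d", seq_len(n_g2))),
    genotype = genotype,
    group = rep(c("G1", "G2"), c(n_g1, n_g2)),
    stim_from = rep(c(1, g2_stim_start), c(n_g1, n_g2))
  )
  attr(design, "n_sessions") <- n_sessions
  design
}

#' Simulate a multi-session cohort to disk
#'
#' Simulates every mouse-session of a [cohort_design()], writing tracking,
#' events and ethogram CSVs plus a manifest. On stimulated sessions the real
#' schedule is delivered; on non-stimulated sessions the sham schedule is
#' emitted (no stimulation applied) so pre-window times exist in every
#' session. The baseline mean speed of session n is
#' `mu_v + drift_lambda * max(0, n - stim_from)`: drift accrues per
#' stimulated session already experienced and persists regardless of
#' same-day stimulation.
#'
#' @param cfg a [sim_config()].
#' @param design a [cohort_design()].
#' @param protocol a [stim_protocol()].
#' @param seed integer seed; per-session seeds are derived from it.
#' @param dir output directory (created if needed).
#' @return manifest tibble (also written to `manifest.csv` in `dir`) with a
#'   `truth` attribute tibble (`mouse_id`, `session_idx`, `mu_v_true`,
#'   `stimulated`).
#' @export
simulate_cohort <- function(cfg = sim_config(), design = cohort_design(),
                            protocol = stim_protocol(), seed = 1,
                            dir = tempfile("cohort")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_sessions <- attr(design, "n_sessions") %||% 24
  rows <- list()
  truth <- list()
  for (mi in seq_len(nrow(design))) {
    m <- design[mi, ]
    for (si in seq_len(n_sessions)) {
      stimulated <- si >= m$stim_from
      n_prior <- max(0, si - m$stim_from)
      mu <- cfg$mu_v + cfg$drift_lambda * n_prior
      sched <- if (stimulated) make_schedule(protocol) else make_sham_schedule(protocol)
      sess <- simulate_session(cfg, schedule = sched, protocol = protocol,
                               seed = (seed * 1009L + mi * 7919L + si * 104729L) %% 2147483629L,
                               mu_v = mu)
      stem <- file.path(dir, sprintf("%s_s%02d", m$mouse_id, si))
      write_tracking(sess$track, paste0(stem, "_tracking.csv"))
      write_events(sess$events, paste0(stem, "_events.csv"))
      write_ethogram(sess$ethogram, paste0(stem, "_ethogram.csv"))
      rows[[length(rows) + 1]] <- tibble(
        mouse_id = m$mouse_id, genotype = m$genotype, group = m$group,
        session_idx = si,
        tracking_path = paste0(stem, "_tracking.csv"),
        events_path = paste0(stem, "_events.csv"),
        ethogram_path = paste0(stem, "_ethogram.csv"))
      truth[[length(truth) + 1]] <- tibble(
        mouse_id = m$mouse_id, session_idx = si,
        mu_v_true = mu, stimulated = stimulated)
    }
  }
  manifest <- bind_rows(rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  attr(manifest, "truth") <- bind_rows(truth)
  manifest
}

#' Simulate a cohort straight to a long-term table
#'
#' In-memory equivalent of [simulate_cohort()] followed by
#' [build_longterm_table()], skipping the CSV round trip; used for
#' calibration studies that fit the session-by-group regression over many
#' replicate cohorts. Per-session seeds follow the same scheme as
#' [simulate_cohort()], so with equal inputs the two paths produce the same
#' table.
#'
#' @inheritParams simulate_cohort
#' @param spec a [window_spec()].
#' @param filter_len median filter length, frames.
#' @return long-term table as in [build_longterm_table()], with a `truth`
#'   attribute (`mouse_id`, `session_idx`, `mu_v_true`, `stimulated`).
#' @export
simulate_longterm_table <- function(cfg = sim_config(), design = cohort_design(),
                                    protocol = stim_protocol(), seed = 1,
                                    spec = window_spec(), filter_len = 5) {
  n_sessions <- attr(design, "n_sessions") %||% 24
  rows <- list()
  truth <- list()
  for (mi in seq_len(nrow(design))) {
    m <- design[mi, ]
    for (si in seq_len(n_sessions)) {
      stimulated <- si >= m$stim_from
      mu <- cfg$mu_v + cfg$drift_lambda * max(0, si - m$stim_from)
      sched <- if (stimulated) make_schedule(protocol) else make_sham_schedule(protocol)
      sess <- simulate_session(cfg, schedule = sched, protocol = protocol,
                               seed = (seed * 1009L + mi * 7919L + si * 104729L) %% 2147483629L,
                               mu_v = mu)
      speed <- compute_speed(sess$track, filter_len)
      ew <- event_windows(speed, sess$events, spec,
                          block_len_s = protocol$block_len_s)
      first_blk <- speed$v[speed$t < protocol$block_len_s]
      rows[[length(rows) + 1]] <- tibble(
        mouse_id = m$mouse_id, group = ifelse(m$group == "G1", 1, 0),
        session_idx = si,
        v_pre = mean(ew$v_pre), v_post = mean(ew$v_post),
        delta = mean(ew$delta),
        v_firstblock = mean(first_blk, na.rm = TRUE))
      truth[[length(truth) + 1]] <- tibble(
        mouse_id = m$mouse_id, session_idx = si,
        mu_v_true = mu, stimulated = stimulated)
    }
  }
  out <- bind_rows(rows)
  attr(out, "truth") <- bind_rows(truth)
  out
}
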