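#' Block/train stimulation protocol
#'
#' The standard session alternates 5-min blocks, always starting with a
#' non-stimulated block. Within each stimulated block a `train_len_s` pulse
#' train is delivered every `train_period_s` (defaults: 3 s trains every
#' 10 s over 30-min sessions, i.e. 3 stimulated blocks x 30 trains = 270 s
#' of stimulation per session).
#'
#' Two pulse-rate presets are in common use and both are provided:
#' `"short_term"` (25 Hz, 10 ms pulses, 5 mW) and `"long_term"` (20 Hz,
#' 10 ms, 5 mW); pass `preset` or set `pulse_hz` directly.
#'
#' @param session_len_s session length, s; must be an integer multiple of
#'   `block_len_s`.
#' @param block_len_s block length, s.
#' @param first_block_stimulated logical; the default `FALSE` starts with a
#'   non-stimulated block.
#' @param train_len_s train duration, s (must be < `train_period_s`).
#' @param train_period_s train period within stimulated blocks, s.
#' @param pulse_hz pulse rate within a train, Hz.
#' @param pulse_width_ms pulse width, ms.
#' @param amplitude_mw light power, mW.
#' @param preset optional preset name overriding `pulse_hz`/`amplitude_mw`.
#' @return `stim_protocol` list.
#' @export
stim_protocol <- function(session_len_s = 1800, block_len_s = 300,
                          first_block_stimulated = FALSE,
                          train_len_s = 3, train_period_s = 10,
                          pulse_hz = 25, pulse_width_ms = 10,
                          amplitude_mw = 5,
                          preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("short_term", "long_term"))
    pulse_hz <- switch(preset, short_term = 25, long_term = 20)
  }
  if (!(train_len_s < train_period_s && train_period_s <= block_len_s)) {
    abort("need train_len_s < train_period_s <= block_len_s")
  }
  n_blocks <- session_len_s / block_len_s
  if (abs(n_blocks - round(n_blocks)) > 1e-9) {
    abort("session_len_s must be an integer multiple of block_len_s")
  }
  structure(list(session_len_s = session_len_s, block_len_s = block_len_s,
                 first_block_stimulated = first_block_stimulated,
                 train_len_s = train_len_s, train_period_s = train_period_s,
                 pulse_hz = pulse_hz, pulse_width_ms = pulse_width_ms,
                 amplitude_mw = amplitude_mw),
            class = "stim_protocol")
}

protocol_blocks <- function(protocol) {
  n_blocks <- as.integer(round(protocol$session_len_s / protocol$block_len_s))
  parity <- if (protocol$first_block_stimulated) 1L else 0L
  tibble(
    block_idx = seq_len(n_blocks),
    start_s = (seq_len(n_blocks) - 1) * protocol$block_len_s,
    stimulated = seq_len(n_blocks) %% 2L == parity
  )
}

make_block_schedule <- function(protocol, stimulated, kind) {
  blocks <- filter(protocol_blocks(protocol), .data$stimulated == !!stimulated)
  n_trains <- floor(protocol$block_len_s / protocol$train_period_s)
  tidyr::crossing(blocks, k = seq_len(n_trains) - 1) %>%
    mutate(onset_s = .data$start_s + .data$k * protocol$train_period_s,
           duration_s = protocol$train_len_s,
           pulse_hz = protocol$pulse_hz,
           pulse_width_ms = protocol$pulse_width_ms,
           amplitude_mw = protocol$amplitude_mw,
           kind = !!kind) %>%
    arrange(.data$onset_s) %>%
    select(all_of(EVENT_COLS))
}

#' Generate the stimulation schedule (and its sham counterpart)
#'
#' `make_schedule()` places one train at `block_start + k * train_period_s`
#' for every stimulated block; `make_sham_schedule()` places events with the
#' identical within-block phase in the non-stimulated blocks (`kind =
#' "sham"`), so real and sham events are exchangeable under the null and the
#' sham set cancels mean reversion in conditioned analyses.
#'
#' @param protocol a [stim_protocol()].
#' @return events tibble (see [read_events()] for columns).
#' @export
make_schedule <- function(protocol) {
  make_block_schedule(protocol, stimulated = TRUE, kind = "real")
}

#' @rdname make_schedule
#' @export
make_sham_schedule <- function(protocol) {
  make_block_schedule(protocol, stimulated = FALSE, kind = "sham")
}

#' Total stimulated time and pulse budget of a protocol
#'
#' `total_stim_time()` is the summed duration of real trains per session.
#' `pulse_budget_fraction()` is the number of pulses per session (one spike
#' assumed per pulse) divided by the daily spike count of a neuron firing at
#' `baseline_hz` — the argument that a daily session adds only a small
#' fractional increase in total spiking.
#'
#' @param protocol a [stim_protocol()].
#' @param baseline_hz baseline firing rate, Hz.
#' @return a single number.
#' @export
total_stim_time <- function(protocol) {
  sum(make_schedule(protocol)$duration_s)
}

#' @rdname total_stim_time
#' @export
pulse_budget_fraction <- function(protocol, baseline_hz = 1) {
  sched <- make_schedule(protocol)
  pulses <- sum(sched$duration_s * sched$pulse_hz)
  pulses / (baseline_hz * 24 * 3600)
}
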