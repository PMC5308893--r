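#' Behavioral state vocabulary
#'
#' Scored states and the mobile/immobile grouping used in state-probability
#' analyses. Jumping and scratching are part of the schema but are rare and
#' can be excluded with the `exclude` argument of the analysis functions.
#'
#' @format Character vectors.
#' @name ethogram_states
#' @export
ethogram_states <- function() ETHOGRAM_STATES

#' @rdname ethogram_states
#' @export
mobile_states <- function() MOBILE_STATES

#' @rdname ethogram_states
#' @export
immobile_states <- function() IMMOBILE_STATES

# total overlap time between a set of [a,b) intervals and one record
interval_overlap <- function(win_a, win_b, rec_a, rec_b) {
  sum(pmax(0, pmin(win_b, rec_b) - pmax(win_a, rec_a)))
}

event_intervals <- function(events, spec, which = c("pre", "post")) {
  which <- match.arg(which)
  if (which == "pre") {
    a <- events$onset_s + spec$pre_start_s
    tibble(start = a, end = a + spec$pre_len_s)
  } else {
    a <- events$onset_s + spec$post_start_s
    tibble(start = a, end = a + spec$post_len_s)
  }
}

#' Behavioral-state probabilities in pre/post windows
#'
#' Probability of each state in the pre- and post-stimulation windows:
#' scored time in the state intersected with the windows, divided by total
#' window time. Records straddling a window boundary contribute
#' proportionally to their overlap. Probabilities over states need not sum
#' to 1 because scoring may leave time unscored.
#'
#' @param records ethogram tibble ([read_ethogram()]).
#' @param events events tibble.
#' @param spec a [window_spec()].
#' @param exclude states to drop from the report (e.g. rare ones).
#' @return tibble `state`, `window` ("pre"/"post"), `prob`.
#' @export
state_probability <- function(records, events, spec = window_spec(),
                              exclude = character(0)) {
  states <- setdiff(setdiff(ETHOGRAM_STATES, "unscored"), exclude)
  per_window <- function(which) {
    win <- event_intervals(events, spec, which)
    total <- sum(win$end - win$start)
    purrr::map_dbl(states, function(s) {
      rec <- filter(records, .data$state == s)
      if (nrow(rec) == 0) return(0)
      ov <- purrr::map2_dbl(rec$onset_s, rec$offset_s,
                            ~ interval_overlap(win$start, win$end, .x, .y))
      sum(ov) / total
    })
  }
  bind_rows(
    tibble(state = states, window = "pre", prob = per_window("pre")),
    tibble(state = states, window = "post", prob = per_window("post"))
  )
}

#' Mobility probability around stimulation onset
#'
#' Fraction of events during which the animal is in a mobile (walking,
#' rearing, jumping) or immobile (resting, digging, grooming, scratching)
#' state, as a function of time from event onset. At each time bin the two
#' probabilities sum to at most 1 (unscored time is counted in neither).
#'
#' @param records ethogram tibble.
#' @param events events tibble.
#' @param range_s alignment range around onset, s.
#' @param bin_s bin width, s.
#' @param exclude states to drop from both groups.
#' @return tibble `time_s`, `p_mobile`, `p_immobile`, `n_events`.
#' @export
mobility_trace <- function(records, events, range_s = c(-5, 10), bin_s = 0.25,
                           exclude = character(0)) {
  if (nrow(events) == 0) abort("need at least one event")
  mob <- setdiff(MOBILE_STATES, exclude)
  imm <- setdiff(IMMOBILE_STATES, exclude)
  centers <- seq(range_s[1] + bin_s / 2, range_s[2] - bin_s / 2, by = bin_s)
  state_at <- function(tt) {
    # state scored at absolute time tt (records are non-overlapping)
    i <- findInterval(tt, records$onset_s)
    out <- rep(NA_character_, length(tt))
    ok <- i >= 1
    ok[ok] <- tt[ok] < records$offset_s[i[ok]]
    out[ok] <- records$state[i[ok & !is.na(ok)]]
    out
  }
  records <- arrange(records, .data$onset_s)
  per_event <- purrr::map(events$onset_s, function(onset) state_at(onset + centers))
  st <- do.call(rbind, per_event)
  tibble(time_s = centers,
         p_mobile = colMeans(matrix(st %in% mob, nrow = nrow(st))),
         p_immobile = colMeans(matrix(st %in% imm, nrow = nrow(st))),
         n_events = nrow(st))
}
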