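#' Peri-event analysis windows
#'
#' Defaults follow the standard design: the *pre* window starts 2 s before
#' stimulation onset and the *post* window 1 s after onset; both are 2 s
#' long. Windows are half-open `[start, start + len)` in time relative to
#' onset; a frame belongs to a window when its timestamp falls inside.
#'
#' @param pre_start_s start of pre window relative to onset (s, negative).
#' @param pre_len_s pre window length (s).
#' @param post_start_s start of post window relative to onset (s).
#' @param post_len_s post window length (s).
#' @return `window_spec` list.
#' @export
window_spec <- function(pre_start_s = -2, pre_len_s = 2,
                        post_start_s = 1, post_len_s = 2) {
  if (pre_start_s + pre_len_s > 0) abort("pre window must end at or before onset")
  if (pre_start_s + pre_len_s > post_start_s) abort("pre and post windows overlap")
  if (pre_len_s <= 0 || post_len_s <= 0) abort("window lengths must be positive")
  structure(list(pre_start_s = pre_start_s, pre_len_s = pre_len_s,
                 post_start_s = post_start_s, post_len_s = post_len_s),
            class = "window_spec")
}

# median filter with shrunken symmetric windows at the boundaries;
# NA centers stay NA, NAs inside a window are dropped from the median
median_filter <- function(v, k) .median_filter(as.numeric(v), as.integer(k))

#' Compute smoothed locomotion speed from tracking
#'
#' Speed at frame i is the centroid displacement from frame i-1 times the
#' frame rate (cm/s), smoothed with a `filter_len`-frame running median
#' (default five frames). The first frame has no displacement and is masked
#' (`NA`); frames following a flagged tracking gap are masked rather than
#' interpolated. Boundary frames use a shrunken symmetric median window.
#'
#' @param track a tracking series from [as_tracking()]/[read_tracking()].
#' @param filter_len odd median filter length in frames.
#' @return `of_speed` tibble with columns `frame`, `t`, `v`.
#' @export
compute_speed <- function(track, filter_len = 5) {
  stopifnot(is_tracking(track))
  if (filter_len %% 2 != 1) abort("filter_len must be odd")
  n <- nrow(track)
  if (n < filter_len) abort("tracking shorter than the filter window")
  fps <- track_fps(track)
  v <- c(NA_real_, sqrt(diff(track$x)^2 + diff(track$y)^2) * fps)
  v[track_gaps(track)] <- NA_real_  # displacement across a gap is undefined
  v <- median_filter(v, as.integer(filter_len))
  structure(tibble(frame = track$frame, t = track$t, v = v),
            fps = fps, filter_len = filter_len,
            class = c("of_speed", class(tibble())))
}

# mean of v over frames with t in [start, start + len); t sorted.
window_mean <- function(t, v, start, len) {
  lo <- findInterval(start - 1e-9, t) + 1L
  hi <- findInterval(start + len - 1e-9, t)
  if (hi < lo) return(NA_real_)
  vv <- v[lo:hi]
  if (anyNA(vv)) return(NA_real_)  # window crosses a masked gap
  mean(vv)
}

#' Per-event pre/post window statistics
#'
#' For every event computes the mean smoothed speed in the pre and post
#' windows and their difference (`delta = v_post - v_pre`). Events whose
#' windows fall outside the session, cross a tracking gap, or (when
#' `block_len_s` is given) cross a block boundary are dropped; the dropped
#' count is available as `attr(x, "n_dropped")`.
#'
#' @param speed an `of_speed` series from [compute_speed()].
#' @param events events tibble ([read_events()] / [make_schedule()]).
#' @param spec a [window_spec()].
#' @param block_len_s optional block length; when given, events whose
#'   windows leave the onset block are dropped.
#' @param track,zonemap optional; when both are given each event is tagged
#'   with `zone_at_onset` via [classify_zone()].
#' @return tibble with one row per retained event: `onset_s`, `kind`,
#'   `block_idx`, `v_pre`, `v_post`, `delta`, `zone_at_onset`.
#' @export
event_windows <- function(speed, events, spec = window_spec(),
                          block_len_s = NULL, track = NULL, zonemap = NULL) {
  stopifnot(inherits(speed, "of_speed"))
  fps <- attr(speed, "fps")
  t0 <- speed$t[1]
  t_end <- speed$t[nrow(speed)] + 1 / fps
  rows <- purrr::pmap(
    list(events$onset_s, events$kind, events$block_idx),
    function(onset, kind, block_idx) {
      pre_a <- onset + spec$pre_start_s
      post_a <- onset + spec$post_start_s
      lo <- pre_a
      hi <- post_a + spec$post_len_s
      if (lo < t0 - 1e-9 || hi > t_end + 1e-9) return(NULL)
      if (!is.null(block_len_s)) {
        blk0 <- floor(onset / block_len_s)
        if (floor(lo / block_len_s) != blk0 ||
            floor((hi - 1e-9) / block_len_s) != blk0) return(NULL)
      }
      v_pre <- window_mean(speed$t, speed$v, pre_a, spec$pre_len_s)
      v_post <- window_mean(speed$t, speed$v, post_a, spec$post_len_s)
      if (is.na(v_pre) || is.na(v_post)) return(NULL)
      tibble(onset_s = onset, kind = kind, block_idx = block_idx,
             v_pre = v_pre, v_post = v_post, delta = v_post - v_pre)
    }
  )
  keep <- !purrr::map_lgl(rows, is.null)
  out <- bind_rows(rows[keep])
  if (nrow(out) == 0) {
    abort("no usable events: check that the window spec matches the protocol")
  }
  if (!is.null(track) && !is.null(zonemap)) {
    idx <- findInterval(out$onset_s, track$t)
    idx[idx < 1] <- 1L
    out$zone_at_onset <- classify_zone(track$x[idx], track$y[idx], zonemap)
  } else {
    out$zone_at_onset <- NA_character_
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Event-aligned average speed trace
#'
#' Aligns the smoothed speed to each event onset (time 0) and averages
#' across events at single-frame resolution, returning mean and SEM per
#' time-from-onset bin.
#'
#' @param speed an `of_speed` series.
#' @param events events tibble.
#' @param range_s alignment range around onset, s.
#' @return tibble `time_s`, `mean`, `sem`, `n_events`.
#' @export
peri_event_trace <- function(speed, events, range_s = c(-5, 10)) {
  stopifnot(inherits(speed, "of_speed"))
  fps <- attr(speed, "fps")
  offs <- seq(ceiling(range_s[1] * fps), floor(range_s[2] * fps))
  n <- nrow(speed)
  mat <- purrr::map(events$onset_s, function(onset) {
    i0 <- findInterval(onset, speed$t)
    idx <- i0 + offs
    ok <- idx >= 1 & idx <= n
    v <- rep(NA_real_, length(offs))
    v[ok] <- speed$v[idx[ok]]
    v
  })
  mat <- do.call(rbind, mat)
  m <- colMeans(mat, na.rm = TRUE)
  nn <- colSums(!is.na(mat))
  s <- apply(mat, 2, sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
  tibble(time_s = offs / fps, mean = m, sem = s, n_events = nn)
}

#' Average event-aligned traces across mice
#'
#' @param traces list of per-mouse traces from [peri_event_trace()] (equal
#'   time grids).
#' @return tibble `time_s`, `mean`, `sem`, `n_mice`.
#' @export
average_traces <- function(traces) {
  mat <- do.call(rbind, purrr::map(traces, "mean"))
  tibble(time_s = traces[[1]]$time_s,
         mean = colMeans(mat, na.rm = TRUE),
         sem = apply(mat, 2, sd, na.rm = TRUE) / sqrt(nrow(mat)),
         n_mice = length(traces))
}
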