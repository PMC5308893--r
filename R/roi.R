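#' Conditioning region of interest
#'
#' The closed-loop protocol stimulates while the body centroid lies inside a
#' rectangle (default 13 x 10.5 cm, centered in the arena). Membership uses
#' the same half-open convention as zones: `x0 <= x < x0 + w`.
#'
#' @param x0,y0 lower-left corner, cm. Defaults center the rectangle in a
#'   50 x 40 cm arena.
#' @param w,h width and height, cm.
#' @param arena_w,arena_h arena dimensions used for the centering default
#'   and the inside-arena check.
#' @return `of_roi` list.
#' @export
roi_rect <- function(w = 13, h = 10.5, x0 = NULL, y0 = NULL,
                     arena_w = 50, arena_h = 40) {
  x0 <- x0 %||% ((arena_w - w) / 2)
  y0 <- y0 %||% ((arena_h - h) / 2)
  if (x0 < 0 || y0 < 0 || x0 + w > arena_w || y0 + h > arena_h) {
    abort("ROI must lie inside the arena")
  }
  structure(list(x0 = x0, y0 = y0, w = w, h = h), class = "of_roi")
}

in_roi <- function(x, y, roi) {
  x >= roi$x0 & x < roi$x0 + roi$w & y >= roi$y0 & y < roi$y0 + roi$h
}

#' ROI visits
#'
#' Maximal intervals during which the centroid is inside the ROI. A visit
#' that is ongoing at session end is closed at the session length; an animal
#' starting inside the ROI gets a first visit with `entry_t` equal to the
#' first timestamp. An optional debounce drops visits shorter than
#' `debounce_s` (default 0: entries/exits counted exactly as membership
#' changes, matching stimulation that terminates immediately on exit).
#'
#' @param track a tracking series.
#' @param roi a [roi_rect()].
#' @param debounce_s minimum visit duration, s.
#' @return tibble `entry_t`, `exit_t`.
#' @export
roi_visits <- function(track, roi, debounce_s = 0) {
  inside <- in_roi(track$x, track$y, roi)
  fps <- track_fps(track)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vi <- which(r$values)
  if (length(vi) == 0) return(tibble(entry_t = numeric(0), exit_t = numeric(0)))
  entry <- track$t[starts[vi]]
  exit_idx <- ends[vi] + 1L
  exit <- ifelse(exit_idx > nrow(track),
                 track$t[nrow(track)] + 1 / fps,  # closed at session end
                 track$t[pmin(exit_idx, nrow(track))])
  out <- tibble(entry_t = entry, exit_t = exit)
  if (debounce_s > 0) out <- filter(out, .data$exit_t - .data$entry_t >= debounce_s)
  out
}

#' Per-session ROI metrics
#'
#' Occupancy, entry and exit rates and mean speeds inside/outside the ROI.
#' Rates follow the closed-loop conditioning definitions: entry rate =
#' number of entries / time spent outside the ROI; exit rate = number of
#' exits / time spent inside. An entry is an outside-to-inside membership
#' transition (a session starting inside the ROI is not an entry), and
#' symmetrically for exits; a rate whose denominator is zero is `NA`.
#'
#' @param track a tracking series.
#' @param roi a [roi_rect()].
#' @param speed optional `of_speed` series for the in/out mean speeds.
#' @param session_len_s session length, s; defaults to the tracked duration.
#' @return one-row tibble: `occupancy_s`, `outside_s`, `n_entries`,
#'   `n_exits`, `entry_rate`, `exit_rate`, `v_inside`, `v_outside`.
#' @export
roi_metrics <- function(track, roi, speed = NULL, session_len_s = NULL) {
  fps <- track_fps(track)
  inside <- in_roi(track$x, track$y, roi)
  dt <- 1 / fps
  occ <- sum(inside) * dt
  total <- session_len_s %||% (nrow(track) * dt)
  outside <- total - occ
  n_entries <- sum(!inside[-length(inside)] & inside[-1])
  n_exits <- sum(inside[-length(inside)] & !inside[-1])
  v_in <- v_out <- NA_real_
  if (!is.null(speed)) {
    v_in <- mean(speed$v[inside], na.rm = TRUE)
    v_out <- mean(speed$v[!inside], na.rm = TRUE)
  }
  tibble(occupancy_s = occ, outside_s = outside,
         n_entries = n_entries, n_exits = n_exits,
         entry_rate = ifelse(outside > 0, n_entries / outside, NA_real_),
         exit_rate = ifelse(occ > 0, n_exits / occ, NA_real_),
         v_inside = v_in, v_outside = v_out)
}

ROI_SESSION_LABELS <- c("pre", "ST1", "ST2", "ST3", "post")

#' ROI conditioning protocol table
#'
#' Computes [roi_metrics()] for every session of a manifest and labels the
#' sessions `pre`, `ST1`–`ST3`, `post` (a `session_label` manifest column
#' takes precedence; otherwise session indices 1–5 are mapped in order).
#'
#' @param manifest manifest tibble ([read_manifest()]).
#' @param roi a [roi_rect()].
#' @param filter_len median filter length for speed.
#' @return tibble: manifest keys + session label + the [roi_metrics()]
#'   columns, one row per mouse-session.
#' @export
roi_protocol_table <- function(manifest, roi, filter_len = 5) {
  if (!"session_label" %in% names(manifest)) {
    if (!all(manifest$session_idx %in% 1:5)) {
      abort("manifest lacks session_label and session_idx is not 1..5")
    }
    manifest$session_label <- ROI_SESSION_LABELS[manifest$session_idx]
  }
  if (any(is.na(manifest$session_label))) abort("missing session label")
  purrr::pmap(manifest, function(...) {
    row <- list(...)
    track <- read_tracking(row$tracking_path)
    speed <- compute_speed(track, filter_len)
    dplyr::bind_cols(
      tibble(mouse_id = row$mouse_id, genotype = row$genotype,
             session_idx = row$session_idx, session_label = row$session_label),
      roi_metrics(track, roi, speed)
    )
  }) %>% bind_rows()
}

#' Cohort summary of the ROI protocol table
#'
#' Mean and SEM of each metric per genotype and session label.
#'
#' @param tbl output of [roi_protocol_table()].
#' @return tidy tibble `genotype`, `session_label`, `metric`, `mean`, `sem`,
#'   `n_mice`.
#' @export
summarise_roi_cohort <- function(tbl) {
  tbl %>%
    tidyr::pivot_longer(all_of(c("occupancy_s", "entry_rate", "exit_rate",
                                 "v_inside", "v_outside")),
                        names_to = "metric", values_to = "value") %>%
    group_by(.data$genotype, .data$session_label, .data$metric) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sem = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
              n_mice = n(), .groups = "drop") %>%
    mutate(session_label = factor(.data$session_label, levels = ROI_SESSION_LABELS)) %>%
    arrange(.data$genotype, .data$session_label, .data$metric)
}
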