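#' Arena zone map
#'
#' Partitions the arena into four zones: *edges*, a thin strip within
#' `edge_margin_cm` of any wall (tracked but normally excluded from
#' analysis); *corners*, the four `band_cm` x `band_cm` squares at the arena
#' corners (minus the edge strip); *periphery*, the remaining `band_cm`-wide
#' band along the walls; and *center*, the interior rectangle. Zone
#' boundaries are half-open (lower/left side inclusive) so every point maps
#' to exactly one zone.
#'
#' The band and margin widths are configuration parameters, not measured
#' quantities; the defaults (10 cm band, 2 cm edge margin) are reasonable
#' for a 50 x 40 cm arena.
#'
#' @param arena_w,arena_h arena dimensions, cm.
#' @param edge_margin_cm width of the edge strip, cm.
#' @param band_cm width of the peripheral band (and corner square side), cm.
#' @return `zone_map` list.
#' @export
zone_map <- function(arena_w = 50, arena_h = 40,
                     edge_margin_cm = 2, band_cm = 10) {
  if (2 * band_cm >= arena_w || 2 * band_cm >= arena_h) {
    abort("band_cm too large for the arena")
  }
  if (edge_margin_cm >= band_cm) abort("edge_margin_cm must be < band_cm")
  structure(list(arena_w = arena_w, arena_h = arena_h,
                 edge_margin_cm = edge_margin_cm, band_cm = band_cm),
            class = "zone_map")
}

ZONES <- c("center", "periphery", "corners", "edges")

#' Classify arena positions into zones
#'
#' @param x,y coordinates, cm (vectorized); must lie inside the arena.
#' @param zonemap a [zone_map()].
#' @return character vector of zone labels
#'   (`"center"`, `"periphery"`, `"corners"`, `"edges"`).
#' @export
classify_zone <- function(x, y, zonemap) {
  w <- zonemap$arena_w; h <- zonemap$arena_h
  e <- zonemap$edge_margin_cm; b <- zonemap$band_cm
  if (any(x < 0 | x > w | y < 0 | y > h)) abort("point outside arena")
  edge <- x < e | x >= w - e | y < e | y >= h - e
  in_xband <- x < b | x >= w - b
  in_yband <- y < b | y >= h - b
  corner <- !edge & in_xband & in_yband
  peri <- !edge & !corner & (in_xband | in_yband)
  out <- rep("center", length(x))
  out[peri] <- "periphery"
  out[corner] <- "corners"
  out[edge] <- "edges"
  out
}

block_of <- function(t, block_len_s) floor(t / block_len_s) + 1L

#' Fractional zone occupancy
#'
#' Time-weighted fraction of frames spent in each zone, optionally per
#' block. Fractions over all four zones sum to 1.
#'
#' @param track a tracking series.
#' @param zonemap a [zone_map()].
#' @param block_len_s optional block length for per-block fractions.
#' @return tibble `block_idx` (0 = whole session), `zone`, `fraction`.
#' @export
occupancy_fractions <- function(track, zonemap, block_len_s = NULL) {
  zone <- classify_zone(track$x, track$y, zonemap)
  blk <- if (is.null(block_len_s)) 0L else block_of(track$t, block_len_s)
  tibble(block_idx = blk, zone = factor(zone, levels = ZONES)) %>%
    dplyr::count(.data$block_idx, .data$zone, .drop = FALSE) %>%
    group_by(.data$block_idx) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    mutate(zone = as.character(.data$zone)) %>%
    select(all_of(c("block_idx", "zone", "fraction")))
}

#' Normalized distance-from-center distribution
#'
#' Per-frame distance from the geometric arena center, normalized by the
#' distance from the center to the wall along the same ray, so both a
#' corner and a wall midpoint normalize to 1. Returns the empirical CDF
#' over frames.
#'
#' @param track a tracking series.
#' @param zonemap a [zone_map()] (for arena dimensions).
#' @return tibble `d_norm` (sorted), `cdf`.
#' @export
center_distance_cdf <- function(track, zonemap) {
  d <- normalized_center_distance(track$x, track$y,
                                  zonemap$arena_w, zonemap$arena_h)
  d <- sort(d)
  tibble(d_norm = d, cdf = seq_along(d) / length(d))
}

normalized_center_distance <- function(x, y, arena_w, arena_h) {
  cx <- arena_w / 2; cy <- arena_h / 2
  dx <- x - cx; dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  # distance from center to wall along (dx, dy): min over the two half-widths
  tx <- ifelse(dx == 0, Inf, cx / abs(dx))
  ty <- ifelse(dy == 0, Inf, cy / abs(dy))
  t_wall <- pmin(tx, ty) * r  # r * scaling = distance to wall along ray
  ifelse(r == 0, 0, r / t_wall)
}

#' Fraction of distance travelled in the center zone
#'
#' Path length of each inter-frame step is assigned to the zone of the
#' step's starting frame; steps across flagged tracking gaps are skipped.
#' Blocks in which the animal travelled no distance are flagged `NA`.
#'
#' @inheritParams occupancy_fractions
#' @return tibble `block_idx` (0 = whole session), `center_fraction`,
#'   `total_cm`.
#' @export
center_travel_fraction <- function(track, zonemap, block_len_s = NULL) {
  n <- nrow(track)
  step <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  gaps <- track_gaps(track)
  if (length(gaps) > 0) step[gaps - 1L] <- NA_real_
  zone <- classify_zone(track$x[-n], track$y[-n], zonemap)
  blk <- if (is.null(block_len_s)) rep(0L, n - 1) else block_of(track$t[-n], block_len_s)
  tibble(block_idx = blk, step = step, zone = zone) %>%
    filter(!is.na(.data$step)) %>%
    group_by(.data$block_idx) %>%
    summarise(total_cm = sum(.data$step),
              center_cm = sum(.data$step[.data$zone == "center"]),
              .groups = "drop") %>%
    mutate(center_fraction = ifelse(.data$total_cm > 0,
                                    .data$center_cm / .data$total_cm, NA_real_)) %>%
    select(all_of(c("block_idx", "center_fraction", "total_cm")))
}

#' Zone-conditioned stimulation effects
#'
#' Groups per-event window statistics by the zone the animal occupied at
#' event onset and by event kind (real/sham), returning per-group mean pre
#' and post speeds and delta. Zones with no events are reported with
#' `n_events = 0`.
#'
#' @param event_stats output of [event_windows()] with `zone_at_onset` set.
#' @return tibble `zone`, `kind`, `n_events`, `v_pre`, `v_post`, `delta`.
#' @export
zone_conditioned_effects <- function(event_stats) {
  if (all(is.na(event_stats$zone_at_onset))) {
    abort("event_stats lacks zone_at_onset; call event_windows() with track and zonemap")
  }
  grid <- tidyr::crossing(zone = ZONES, kind = unique(event_stats$kind))
  event_stats %>%
    group_by(zone = .data$zone_at_onset, kind = .data$kind) %>%
    summarise(n_events = n(),
              v_pre = mean(.data$v_pre), v_post = mean(.data$v_post),
              delta = mean(.data$delta), .groups = "drop") %>%
    dplyr::right_join(grid, by = c("zone", "kind")) %>%
    mutate(n_events = tidyr::replace_na(.data$n_events, 0L)) %>%
    arrange(factor(.data$zone, levels = ZONES), .data$kind)
}
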