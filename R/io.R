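#' File formats
#'
#' All pipeline files are plain UTF-8 CSV (comma separator, `.` decimal).
#' Tracking files carry `#`-prefixed metadata lines before the header giving
#' the frame rate and arena dimensions:
#'
#' ```
#' # fps: 60
#' # arena_w: 50
#' # arena_h: 40
#' frame,t,x,y
#' ```
#'
#' Coordinates are cm in the arena frame: origin at the bottom-left corner,
#' x in `[0, arena_w]`, y in `[0, arena_h]`, time in seconds from session
#' start, frames 0-based.
#'
#' @name openfieldr-formats
NULL

ETHOGRAM_STATES <- c("walking", "rearing", "jumping", "resting",
                     "digging", "grooming", "scratching", "unscored")
MOBILE_STATES <- c("walking", "rearing", "jumping")
IMMOBILE_STATES <- c("resting", "digging", "grooming", "scratching")

#' Construct a validated tracking series
#'
#' A tracking series is a tibble with columns `frame` (0-based integer),
#' `t` (s), `x`, `y` (cm), plus attributes `fps`, `arena_w`, `arena_h` and
#' `gaps`. A *gap* is a frame whose time step from the previous frame
#' deviates from `1/fps` by more than 1e-6 s; gaps are flagged (and later
#' masked in speed computation), never interpolated.
#'
#' @param df data frame with columns `frame`, `t`, `x`, `y`.
#' @param fps frames per second.
#' @param arena_w,arena_h arena width and height in cm.
#' @return A `of_tracking` tibble.
#' @export
as_tracking <- function(df, fps, arena_w, arena_h) {
  df <- as_tibble(df)
  need <- c("frame", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("tracking data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(df) >= 2 && any(diff(df$t) <= 0)) {
    bad <- which(diff(df$t) <= 0)[1]
    abort(sprintf("t must be strictly increasing (violated at frame %d)",
                  df$frame[bad + 1]))
  }
  out_x <- df$x < 0 | df$x > arena_w
  out_y <- df$y < 0 | df$y > arena_h
  if (any(out_x | out_y)) {
    bad <- df$frame[which(out_x | out_y)]
    abort(sprintf("coordinates outside arena [0,%g]x[0,%g] at frame(s): %s",
                  arena_w, arena_h,
                  paste(head(bad, 10), collapse = ", ")))
  }
  gaps <- integer(0)
  if (nrow(df) >= 2) {
    dt <- diff(df$t)
    gaps <- which(abs(dt - 1 / fps) > 1e-6) + 1L  # index of frame AFTER the gap
  }
  structure(df,
            fps = fps, arena_w = arena_w, arena_h = arena_h, gaps = gaps,
            class = c("of_tracking", class(df)))
}

#' @rdname as_tracking
#' @param x object to test
#' @export
is_tracking <- function(x) inherits(x, "of_tracking")

track_fps <- function(track) attr(track, "fps")
track_arena <- function(track) c(w = attr(track, "arena_w"), h = attr(track, "arena_h"))
track_gaps <- function(track) attr(track, "gaps")

read_meta_lines <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", meta_lines))
  vals <- list()
  for (m in kv) if (length(m) == 3) vals[[m[2]]] <- m[3]
  vals
}

read_body <- function(path, col_types) {
  tryCatch(
    readr::read_csv(path, comment = "#", col_types = col_types,
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)))
  )
}

check_parse_problems <- function(df, path, n_meta) {
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    abort(sprintf("malformed row in %s at file line %d: %s",
                  path, pr$row[1] + n_meta + 1L, pr$expected[1]))
  }
  df
}

#' Read and write tracking CSV
#'
#' @param path file path.
#' @return `read_tracking()` returns a validated tracking series (see
#'   [as_tracking()]); gaps are flagged in the `gaps` attribute.
#' @export
read_tracking <- function(path) {
  meta <- read_meta_lines(path)
  for (k in c("fps", "arena_w", "arena_h")) {
    if (is.null(meta[[k]])) abort(sprintf("%s: missing '# %s:' metadata line", path, k))
  }
  df <- read_body(path, readr::cols(frame = "i", t = "d", x = "d", y = "d"))
  df <- check_parse_problems(df, path, 3L)
  as_tracking(df,
              fps = as.numeric(meta$fps),
              arena_w = as.numeric(meta$arena_w),
              arena_h = as.numeric(meta$arena_h))
}

#' @rdname read_tracking
#' @param track tracking series.
#' @export
write_tracking <- function(track, path) {
  stopifnot(is_tracking(track))
  ar <- track_arena(track)
  hdr <- c(sprintf("# fps: %s", format(track_fps(track))),
           sprintf("# arena_w: %s", format(ar[["w"]])),
           sprintf("# arena_h: %s", format(ar[["h"]])))
  writeLines(hdr, path)
  readr::write_csv(as_tibble(as.data.frame(track)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

EVENT_COLS <- c("onset_s", "duration_s", "pulse_hz", "pulse_width_ms",
                "amplitude_mw", "kind", "block_idx")

validate_events <- function(ev) {
  if (nrow(ev) == 0) return(ev)
  if (any(ev$duration_s <= 0)) abort("event duration_s must be > 0")
  if (any(ev$pulse_hz < 0)) abort("event pulse_hz must be >= 0")
  if (!all(ev$kind %in% c("real", "sham"))) {
    abort("event kind must be 'real' or 'sham'")
  }
  ev <- arrange(ev, .data$onset_s)
  re <- filter(ev, .data$kind == "real")
  if (nrow(re) >= 2) {
    ends <- re$onset_s + re$duration_s
    if (any(re$onset_s[-1] < ends[-nrow(re)] - 1e-12)) {
      i <- which(re$onset_s[-1] < ends[-nrow(re)] - 1e-12)[1]
      abort(sprintf("real events overlap: event at %g s runs past onset of event at %g s",
                    re$onset_s[i], re$onset_s[i + 1]))
    }
  }
  ev
}

#' Read and write stimulation event CSV
#'
#' Columns: `onset_s, duration_s, pulse_hz, pulse_width_ms, amplitude_mw,
#' kind, block_idx`. `kind` defaults to `"real"` when absent. Events are
#' returned sorted by onset; overlapping real events raise an error.
#'
#' @param path file path.
#' @return tibble of events.
#' @export
read_events <- function(path) {
  hdr <- strsplit(grep("^#", readLines(path, n = 10L, warn = FALSE),
                       value = TRUE, invert = TRUE)[1], ",")[[1]]
  types <- if ("kind" %in% hdr) readr::cols(.default = "d", kind = "c")
           else readr::cols(.default = "d")
  df <- read_body(path, types)
  df <- check_parse_problems(df, path, 0L)
  if (!"kind" %in% names(df)) df$kind <- "real"
  df$kind[is.na(df$kind)] <- "real"
  if (!"block_idx" %in% names(df)) df$block_idx <- NA_real_
  miss <- setdiff(setdiff(EVENT_COLS, c("kind", "block_idx")), names(df))
  if (length(miss) > 0) {
    abort(paste0(path, ": events file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  validate_events(as_tibble(df[EVENT_COLS]))
}

#' @rdname read_events
#' @param events events tibble.
#' @export
write_events <- function(events, path) {
  validate_events(as_tibble(events)[EVENT_COLS])
  readr::write_csv(as_tibble(events)[EVENT_COLS], path)
  invisible(path)
}

validate_ethogram <- function(rec) {
  if (nrow(rec) == 0) return(rec)
  bad <- setdiff(unique(rec$state), ETHOGRAM_STATES)
  if (length(bad) > 0) {
    abort(sprintf("unknown ethogram state(s) %s; allowed: %s",
                  paste(bad, collapse = ", "),
                  paste(ETHOGRAM_STATES, collapse = ", ")))
  }
  if (any(rec$offset_s <= rec$onset_s)) abort("ethogram record offset_s must exceed onset_s")
  rec <- arrange(rec, .data$onset_s)
  if (nrow(rec) >= 2 && any(rec$onset_s[-1] < rec$offset_s[-nrow(rec)] - 1e-12)) {
    abort("ethogram records overlap")
  }
  rec
}

#' Read and write ethogram CSV
#'
#' Columns `onset_s, offset_s, state`; records must be non-overlapping and
#' states drawn from the documented vocabulary (walking, rearing, jumping,
#' resting, digging, grooming, scratching, unscored).
#'
#' @param path file path.
#' @return tibble of ethogram records.
#' @export
read_ethogram <- function(path) {
  df <- read_body(path, readr::cols(onset_s = "d", offset_s = "d", state = "c"))
  df <- check_parse_problems(df, path, 0L)
  validate_ethogram(as_tibble(df[c("onset_s", "offset_s", "state")]))
}

#' @rdname read_ethogram
#' @param records ethogram tibble.
#' @export
write_ethogram <- function(records, path) {
  validate_ethogram(as_tibble(records)[c("onset_s", "offset_s", "state")])
  readr::write_csv(as_tibble(records)[c("onset_s", "offset_s", "state")], path)
  invisible(path)
}

MANIFEST_COLS <- c("mouse_id", "genotype", "group", "session_idx",
                   "tracking_path", "events_path", "ethogram_path")

validate_manifest <- function(mf) {
  if (!all(mf$genotype %in% c("SERT-Cre", "WT"))) {
    abort("manifest genotype must be 'SERT-Cre' or 'WT'")
  }
  if (!all(mf$group %in% c("G1", "G2", "none"))) {
    abort("manifest group must be 'G1', 'G2' or 'none'")
  }
  if (any(mf$session_idx < 1)) abort("session_idx must be >= 1")
  key <- paste(mf$mouse_id, mf$session_idx)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (mouse_id, session_idx): %s", key[duplicated(key)][1]))
  }
  mf
}

#' Read and write session manifest CSV
#'
#' One row per mouse-session: `mouse_id, genotype, group, session_idx,
#' tracking_path, events_path, ethogram_path` (the last may be empty). An
#' optional `session_label` column (e.g. pre/ST1/ST2/ST3/post for the ROI
#' protocol) is preserved when present.
#'
#' @param path file path.
#' @return manifest tibble.
#' @export
read_manifest <- function(path) {
  df <- read_body(path, readr::cols(.default = "c", session_idx = "i"))
  df <- check_parse_problems(df, path, 0L)
  if (!"ethogram_path" %in% names(df)) df$ethogram_path <- NA_character_
  miss <- setdiff(setdiff(MANIFEST_COLS, "ethogram_path"), names(df))
  if (length(miss) > 0) {
    abort(paste0(path, ": manifest lacks column(s): ", paste(miss, collapse = ", ")))
  }
  keep <- c(MANIFEST_COLS, intersect("session_label", names(df)))
  validate_manifest(as_tibble(df[keep]))
}

#' @rdname read_manifest
#' @param manifest manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  mf <- as_tibble(manifest)
  keep <- c(MANIFEST_COLS, intersect("session_label", names(mf)))
  validate_manifest(mf[keep])
  readr::write_csv(mf[keep], path)
  invisible(path)
}

#' Read a YAML analysis configuration
#'
#' A config file may hold `protocol`, `zones`, `roi` and `sim` blocks whose
#' keys are the arguments of [stim_protocol()], [zone_map()], [roi_rect()]
#' and [sim_config()] respectively; missing keys fall back to the defaults.
#'
#' @param path YAML file.
#' @return list with elements `protocol`, `zones`, `roi`, `sim` (constructed
#'   objects) plus `raw` (the parsed YAML).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(block, ctor) do.call(ctor, as.list(block %||% list()))
  list(
    protocol = build(raw$protocol, stim_protocol),
    zones = build(raw$zones, zone_map),
    roi = if (!is.null(raw$roi)) build(raw$roi, roi_rect) else NULL,
    sim = build(raw$sim, sim_config),
    raw = raw
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
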