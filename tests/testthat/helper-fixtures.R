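# fixtures built in code; no data files

# tracking series from explicit coordinates at a given frame rate
toy_track <- function(x, y, fps = 10, arena_w = 50, arena_h = 40, t = NULL) {
  n <- length(x)
  as_tracking(tibble::tibble(frame = seq_len(n) - 1L,
                             t = t %||% ((seq_len(n) - 1) / fps),
                             x = x, y = y),
              fps = fps, arena_w = arena_w, arena_h = arena_h)
}

# straight path at constant speed (cm/s) along +x, starting at (x0, y0)
constant_speed_track <- function(v_cms, n, fps = 10, x0 = 1, y0 = 20,
                                 arena_w = 5000, arena_h = 40) {
  step <- v_cms / fps
  toy_track(x0 + step * (seq_len(n) - 1), rep(y0, n),
            fps = fps, arena_w = arena_w, arena_h = arena_h)
}

# tracking whose smoothed speed is (approximately) a given piecewise value:
# path along +x with per-frame step v(t)/fps
speed_profile_track <- function(v_of_t, n, fps = 10, arena_w = 1e6) {
  tt <- (seq_len(n) - 1) / fps
  steps <- v_of_t(tt) / fps
  x <- 1 + cumsum(c(0, steps[-1]))
  toy_track(x, rep(10, n), fps = fps, arena_w = arena_w, arena_h = 40)
}

write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

tracking_csv_lines <- function(df, fps = 10, arena_w = 50, arena_h = 40) {
  c(sprintf("# fps: %s", fps),
    sprintf("# arena_w: %s", arena_w),
    sprintf("# arena_h: %s", arena_h),
    "frame,t,x,y",
    sprintf("%d,%s,%s,%s", df$frame, format(df$t), format(df$x), format(df$y)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
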