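test_that("stationary animal has zero speed; first frame is masked", {
  tr <- toy_track(rep(10, 20), rep(10, 20))
  sp <- compute_speed(tr)
  expect_true(is.na(sp$v[1]))
  expect_true(all(sp$v[-1] == 0))
})

test_that("straight path at 0.1 cm/frame and 60 fps gives 6 cm/s", {
  tr <- constant_speed_track(6, 100, fps = 60)
  sp <- compute_speed(tr)
  expect_equal(sp$v[-1], rep(6, 99))
})

test_that("median filter rejects a single-frame tracking glitch", {
  tr <- constant_speed_track(6, 50, fps = 10)
  x <- tr$x
  x[25] <- x[25] + 10  # one-frame 10 cm jump
  glitchy <- toy_track(x, tr$y, fps = 10, arena_w = 5000)
  raw <- c(NA, sqrt(diff(glitchy$x)^2 + diff(glitchy$y)^2)) * 10
  expect_gt(max(raw, na.rm = TRUE), 50)        # unfiltered oracle shows the spike
  sp <- compute_speed(glitchy, filter_len = 5)
  expect_lt(max(sp$v, na.rm = TRUE), 10)       # filtered speed does not
})

test_that("filtered speed equals a plain-R median filter oracle", {
  withr::local_seed(42)
  ref_filter <- function(v, k) {
    n <- length(v); h <- (k - 1) %/% 2
    out <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (is.na(v[i])) next
      hi <- min(h, i - 1, n - i)
      w <- v[(i - hi):(i + hi)]
      w <- w[!is.na(w)]
      if (length(w)) out[i] <- median(w)
    }
    out
  }
  for (k in c(3, 5, 7)) {
    v <- rnorm(200)
    v[sample(200, 10)] <- NA
    expect_equal(openfieldr:::median_filter(v, k), ref_filter(v, k))
  }
})

test_that("speed is invariant to translation and 90-degree rotation", {
  withr::local_seed(7)
  x <- 10 + cumsum(rnorm(100, 0, 0.05))
  y <- 10 + cumsum(rnorm(100, 0, 0.05))
  base <- compute_speed(toy_track(x, y))$v
  shifted <- compute_speed(toy_track(x + 5, y + 3))$v
  rotated <- compute_speed(toy_track(y, 50 - x, arena_w = 40, arena_h = 50))$v
  expect_equal(shifted, base)
  expect_equal(rotated, base)
})

test_that("speed is masked across flagged tracking gaps", {
  t <- (0:19) / 10
  t[11:20] <- t[11:20] + 0.5  # gap between frames 10 and 11
  tr <- toy_track(seq(1, 2, length.out = 20), rep(5, 20), t = t)
  sp <- compute_speed(tr)
  expect_true(is.na(sp$v[11]))
})

test_that("event windows follow the pre [-2,0) / post [+1,+3) convention", {
  # speed 6 before onset at t = 100, 3 after
  tr <- speed_profile_track(function(t) ifelse(t < 100, 6, 3), 1100, fps = 10)
  sp <- compute_speed(tr)
  ev <- tibble::tibble(onset_s = 100, duration_s = 3, pulse_hz = 25,
                       pulse_width_ms = 10, amplitude_mw = 5,
                       kind = "real", block_idx = 1)
  ew <- event_windows(sp, ev)
  # brute-force oracle over the same frames
  pre_frames <- sp$t >= 98 & sp$t < 100
  post_frames <- sp$t >= 101 & sp$t < 103
  expect_equal(ew$v_pre, mean(sp$v[pre_frames]))
  expect_equal(ew$v_post, mean(sp$v[post_frames]))
  expect_equal(ew$v_pre, 6, tolerance = 1e-10)
  expect_equal(ew$v_post, 3, tolerance = 1e-10)
  expect_equal(ew$delta, ew$v_post - ew$v_pre)
})

test_that("windowed means match a brute-force mask oracle on random events", {
  withr::local_seed(3)
  tr <- speed_profile_track(function(t) 3 + 2 * sin(t / 7), 4000, fps = 10)
  sp <- compute_speed(tr)
  onsets <- sort(runif(40, 10, 380))
  ev <- tibble::tibble(onset_s = onsets, duration_s = 3, pulse_hz = 25,
                       pulse_width_ms = 10, amplitude_mw = 5,
                       kind = "real", block_idx = 1)
  ew <- event_windows(sp, ev)
  spec <- window_spec()
  for (i in seq_len(nrow(ew))) {
    a <- ew$onset_s[i] + spec$pre_start_s
    oracle <- mean(sp$v[sp$t >= a & sp$t < a + spec$pre_len_s])
    expect_equal(ew$v_pre[i], oracle, tolerance = 1e-10)
    b <- ew$onset_s[i] + spec$post_start_s
    oracle <- mean(sp$v[sp$t >= b & sp$t < b + spec$post_len_s])
    expect_equal(ew$v_post[i], oracle, tolerance = 1e-10)
  }
})

test_that("events with out-of-session or cross-block windows are dropped and counted", {
  tr <- constant_speed_track(5, 600 * 10, fps = 10)
  sp <- compute_speed(tr)
  ev <- tibble::tibble(onset_s = c(1, 300, 100), duration_s = 3, pulse_hz = 25,
                       pulse_width_ms = 10, amplitude_mw = 5,
                       kind = "real", block_idx = c(1, 2, 1))
  ew <- event_windows(sp, ev, block_len_s = 300)
  # onset 1: pre window starts before the session; onset 300: pre in block 1
  expect_equal(nrow(ew), 1)
  expect_equal(ew$onset_s, 100)
  expect_equal(attr(ew, "n_dropped"), 2)
  expect_error(event_windows(sp, ev[1, ], block_len_s = 300), "no usable events")
})

test_that("constant speed gives a flat aligned trace; one event is its own trace", {
  tr <- constant_speed_track(4, 2000, fps = 10)
  sp <- compute_speed(tr)
  ev <- tibble::tibble(onset_s = c(50, 100, 150), duration_s = 3, pulse_hz = 25,
                       pulse_width_ms = 10, amplitude_mw = 5,
                       kind = "real", block_idx = 1)
  trace <- peri_event_trace(sp, ev)
  expect_true(all(abs(trace$mean - 4) < 1e-10))
  expect_true(all(trace$sem < 1e-10))

  single <- peri_event_trace(sp, ev[1, ], range_s = c(-2, 2))
  i0 <- findInterval(50, sp$t)
  offs <- seq(-2 * 10, 2 * 10)
  expect_equal(single$mean, sp$v[i0 + offs])
})

test_that("window specs are validated", {
  expect_error(window_spec(pre_start_s = -1, pre_len_s = 2), "onset")
  expect_error(window_spec(post_start_s = -1, post_len_s = 0.5), "overlap")
})
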