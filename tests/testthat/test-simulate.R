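test_that("identical seed and config give identical sessions", {
  cfg <- sim_config(fps = 20)
  pro <- stim_protocol(session_len_s = 600)
  a <- simulate_session(cfg, protocol = pro, seed = 123)
  b <- simulate_session(cfg, protocol = pro, seed = 123)
  expect_identical(a$track$x, b$track$x)
  expect_identical(a$ethogram, b$ethogram)
  c <- simulate_session(cfg, protocol = pro, seed = 124)
  expect_false(identical(a$track$x, c$track$x))
})

test_that("positions stay inside the arena and true speeds are non-negative", {
  cfg <- sim_config(fps = 30, w_wall = 2)  # strong wall attraction
  s <- simulate_session(cfg, protocol = stim_protocol(session_len_s = 600), seed = 5)
  expect_true(all(s$track$x >= 0 & s$track$x <= cfg$arena_w))
  expect_true(all(s$track$y >= 0 & s$track$y <= cfg$arena_h))
  expect_true(all(s$truth$state$v_true >= 0))
})

test_that("ethogram records equal the true state path", {
  cfg <- sim_config(fps = 10)
  s <- simulate_session(cfg, protocol = stim_protocol(session_len_s = 300), seed = 8)
  # reconstruct per-frame states from the records; must match truth exactly
  st <- s$truth$state
  lab <- character(nrow(st))
  for (i in seq_len(nrow(s$ethogram))) {
    sel <- st$t >= s$ethogram$onset_s[i] & st$t < s$ethogram$offset_s[i]
    lab[sel] <- s$ethogram$state[i]
  }
  expect_equal(lab, st$state)
})

test_that("no-effect simulation yields near-zero delta; suppression halves speed", {
  pro <- stim_protocol(session_len_s = 1800)
  null_cfg <- sim_config(fps = 20, g_stim = 1, rest_boost = 1)
  s <- simulate_session(null_cfg, protocol = pro, seed = 301)
  sp <- compute_speed(s$track)
  ew <- event_windows(sp, s$events, block_len_s = 300)
  md <- mouse_delta(ew)
  expect_lt(abs(md$delta), 3 * sd(ew$delta) / sqrt(nrow(ew)))

  # g = 0.5 with fast reversion and walking only: v_post ~ 0.5 v_pre
  eff_cfg <- sim_config(fps = 20, g_stim = 0.5, theta_per_s = 2,
                        states = state_model_walking_only(),
                        tau_on_s = 0.2, rest_boost = 1)
  s2 <- simulate_session(eff_cfg, protocol = pro, seed = 302)
  sp2 <- compute_speed(s2$track)
  ew2 <- event_windows(sp2, s2$events, block_len_s = 300)
  md2 <- mouse_delta(ew2)
  expect_equal(md2$v_post_mean / md2$v_pre_mean, 0.5, tolerance = 0.08)
})

test_that("sham events on unperturbed blocks show no effect", {
  pro <- stim_protocol(session_len_s = 1800)
  s <- simulate_session(sim_config(fps = 20), protocol = pro, seed = 303)
  sp <- compute_speed(s$track)
  sham <- event_windows(sp, make_sham_schedule(pro), block_len_s = 300)
  md <- mouse_delta(sham)
  expect_lt(abs(md$delta), 3 * sd(sham$delta) / sqrt(nrow(sham)))
})

test_that("ROI session events exactly equal the ROI visit intervals", {
  roi <- roi_rect()
  cfg <- sim_config(fps = 20, g_stim = 0.5)
  s <- simulate_roi_session(cfg, roi, session_len_s = 300, seed = 44)
  v <- roi_visits(s$track, roi)
  expect_equal(s$events$onset_s, v$entry_t)
  expect_equal(s$events$onset_s + s$events$duration_s, v$exit_t,
               tolerance = 1e-9)
})

test_that("cohort files round-trip and drift enters only stimulated mice", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(fps = 10, drift_lambda = 0.5,
                    states = state_model_walking_only())
  des <- cohort_design(n_g1 = 1, n_g2 = 1, n_sessions = 3, g2_stim_start = 4)
  mf <- simulate_cohort(cfg, des, stim_protocol(session_len_s = 600),
                        seed = 2, dir = dir)
  expect_equal(nrow(mf), 6)
  expect_true(all(file.exists(mf$tracking_path)))
  truth <- attr(mf, "truth")
  g1 <- truth$mu_v_true[truth$mouse_id == "g1_m01"]
  g2 <- truth$mu_v_true[truth$mouse_id == "g2_m01"]
  expect_equal(g1, cfg$mu_v + 0.5 * (0:2))
  expect_equal(g2, rep(cfg$mu_v, 3))
  # the manifest on disk reads back identically
  mf2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(as.data.frame(mf2), as.data.frame(mf), ignore_attr = TRUE)
})

test_that("in-memory long-term table agrees with the file round-trip path", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(fps = 10, states = state_model_walking_only())
  des <- cohort_design(n_g1 = 1, n_g2 = 1, n_sessions = 2, g2_stim_start = 3)
  pro <- stim_protocol(session_len_s = 600)
  mf <- simulate_cohort(cfg, des, pro, seed = 6, dir = dir)
  tab_file <- build_longterm_table(mf)
  tab_mem <- simulate_longterm_table(cfg, des, pro, seed = 6)
  expect_equal(as.data.frame(tab_mem), as.data.frame(tab_file),
               tolerance = 1e-10, ignore_attr = TRUE)
})
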