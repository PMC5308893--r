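mk_table <- function(v_pre_fun, mice_g1 = 2, mice_g2 = 2, sessions = 6) {
  rows <- list()
  for (g in c(1, 0)) {
    n_mice <- if (g == 1) mice_g1 else mice_g2
    for (m in seq_len(n_mice)) {
      id <- sprintf("g%d_m%d", 2 - g, m)
      for (s in seq_len(sessions)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          mouse_id = id, group = g, session_idx = s,
          v_pre = v_pre_fun(s, g, m), v_post = v_pre_fun(s, g, m) - 2,
          delta = -2, v_firstblock = v_pre_fun(s, g, m))
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("exact linear data is recovered to machine precision", {
  tab <- mk_table(function(s, g, m) 5 + 0.1 * s * g)
  fit <- fit_longterm(tab)
  # summary.lm warns about the (intentionally) perfect fit
  ti <- suppressWarnings(tidy(fit))
  expect_equal(ti$estimate, c(5, 0, 0, 0.1), tolerance = 1e-12)
  expect_equal(suppressWarnings(glance(fit))$nobs, nrow(tab))
})

test_that("coefficients match a normal-equations oracle", {
  withr::local_seed(15)
  tab <- mk_table(function(s, g, m) 5 + 0.2 * s + 0.5 * g + rnorm(1, 0, 0.5))
  fit <- fit_longterm(tab)
  X <- cbind(1, tab$session_idx, tab$group, tab$session_idx * tab$group)
  beta <- solve(t(X) %*% X, t(X) %*% tab$v_pre)
  expect_equal(tidy(fit)$estimate, as.numeric(beta), tolerance = 1e-10)
})

test_that("single-group tables are rejected", {
  tab <- mk_table(function(s, g, m) 5, mice_g2 = 0)
  expect_error(fit_longterm(tab), "group")
})

test_that("permuted group labels kill the interaction", {
  withr::local_seed(16)
  tab <- mk_table(function(s, g, m) 5 + 0.3 * s * g + rnorm(1, 0, 0.3),
                  mice_g1 = 3, mice_g2 = 3, sessions = 12)
  b3 <- tidy(fit_longterm(tab))$estimate[4]
  perm_b3 <- replicate(200, {
    shuffled <- tab %>%
      dplyr::distinct(mouse_id) %>%
      dplyr::mutate(new_group = sample(rep(c(1, 0), each = 3)))
    t2 <- dplyr::left_join(tab, shuffled, by = "mouse_id") %>%
      dplyr::mutate(group = new_group)
    tidy(fit_longterm(t2))$estimate[4]
  })
  expect_lt(abs(mean(perm_b3)), abs(b3) / 4)
  # true labeling sits at the top of the permutation null (random shuffles
  # occasionally reproduce the true labels, so >= rather than >)
  expect_gte(b3, quantile(perm_b3, 0.975))
})

test_that("early/late contrast: identical windows differ by zero; drift shows late rise", {
  tab <- mk_table(function(s, g, m) 6 + 0.01 * m)
  el <- early_late_contrast(tab, "v_pre", early = 1:3, late = 4:6)
  expect_equal(el$diff, c(0, 0))

  drift <- mk_table(function(s, g, m) 6 + 0.4 * s * g + 0.01 * m, sessions = 12)
  el2 <- early_late_contrast(drift, "v_pre", early = 1:4, late = 9:12)
  expect_gt(el2$diff[el2$group == 1], 2)
  expect_equal(el2$diff[el2$group == 0], 0)
})

test_that("correlation procedure A: pair bookkeeping and degenerate predictor", {
  # 4 sessions per mouse -> 2 interior sessions -> 2 pairs per mouse
  tab <- mk_table(function(s, g, m) 5 + s + 0.01 * m, sessions = 4)
  res <- short_long_correlation_A(tab)
  expect_equal(res$n_pairs, 2 * 4)
  # delta constant: regression has nothing to explain
  expect_equal(res$p, 1)

  per <- short_long_correlation_A(tab, pool = FALSE)
  expect_equal(nrow(per), 4)
  expect_true(all(per$n_pairs == 2))
})

test_that("correlation procedure B: perfectly linear v_pre gives R^2 = 0", {
  tab <- mk_table(function(s, g, m) 5 + 0.3 * s, sessions = 6)
  res <- short_long_correlation_B(tab)
  expect_equal(res$r_squared, 0)
  expect_equal(res$n_pairs, (6 - 1) * 4)
})

test_that("procedure B recovers a deliberate next-day coupling", {
  withr::local_seed(19)
  # v_pre(n+1) = trend + c * delta(n) + noise, coupling c = 0.8
  cpl <- 0.8
  rows <- list()
  for (m in 1:6) {
    deltas <- rnorm(20, -2, 1)
    v <- numeric(20)
    v[1] <- 6
    for (s in 2:20) v[s] <- 6 + 0.05 * s + cpl * deltas[s - 1] + rnorm(1, 0, 0.1)
    rows[[m]] <- tibble::tibble(mouse_id = paste0("m", m),
                                group = as.numeric(m <= 3), session_idx = 1:20,
                                v_pre = v, v_post = v + deltas, delta = deltas,
                                v_firstblock = v)
  }
  tab <- dplyr::bind_rows(rows)
  res <- short_long_correlation_B(tab)
  expect_equal(res$slope, cpl, tolerance = 0.15)
  expect_lt(res$p, 1e-6)
  # procedures A and B agree in sign on coupled data
  resA <- short_long_correlation_A(tab)
  expect_gt(resA$slope * res$slope, 0)
})

test_that("correlations from uncoupled simulation are near zero", {
  cfg <- sim_config(fps = 15, states = state_model_walking_only(),
                    drift_lambda = 0.15)
  des <- cohort_design(n_g1 = 3, n_g2 = 0, n_sessions = 12, g2_stim_start = 99)
  pro <- stim_protocol(session_len_s = 600)
  tab <- simulate_longterm_table(cfg, des, pro, seed = 71)
  resA <- short_long_correlation_A(tab)
  expect_equal(resA$n_pairs, 3 * 10)
  expect_lt(resA$r_squared, 0.2)
  resB <- short_long_correlation_B(tab)
  expect_lt(resB$r_squared, 0.2)
})

test_that("build_longterm_table produces one row per mouse-session with cross-module delta", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(fps = 10)
  des <- cohort_design(n_g1 = 1, n_g2 = 1, n_sessions = 3, g2_stim_start = 1)
  pro <- stim_protocol(session_len_s = 600)
  mf <- simulate_cohort(cfg, des, pro, seed = 3, dir = dir)
  tab <- build_longterm_table(mf)
  expect_equal(nrow(tab), 6)
  # delta column equals an independent mouse_delta recomputation
  row <- mf[3, ]
  sp <- compute_speed(read_tracking(row$tracking_path))
  ew <- event_windows(sp, dplyr::filter(read_events(row$events_path), kind == "real"),
                      block_len_s = 300)
  md <- mouse_delta(ew)
  sel <- tab$mouse_id == row$mouse_id & tab$session_idx == row$session_idx
  expect_equal(tab$delta[sel], md$delta, tolerance = 1e-12)
})
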