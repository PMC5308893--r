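#' Build the per-mouse-per-session long-term table
#'
#' For every manifest row, reads the session files and computes the mean
#' pre-window speed `v_pre`, mean post-window speed `v_post`, their
#' difference `delta`, and `v_firstblock`, the mean speed during the first
#' (never-stimulated) block. Windows come from the real events when the
#' session was stimulated and from the sham-timed events otherwise, so
#' `v_pre` is defined in every session. Sessions with unreadable files are
#' excluded with a warning.
#'
#' @param manifest manifest tibble ([read_manifest()] / [simulate_cohort()]).
#' @param spec a [window_spec()].
#' @param block_len_s block length for first-block statistics and window
#'   checks, s.
#' @param filter_len median filter length, frames.
#' @return tibble `mouse_id`, `group` (1 = G1, 0 = G2), `session_idx`,
#'   `v_pre`, `v_post`, `delta`, `v_firstblock`.
#' @export
build_longterm_table <- function(manifest, spec = window_spec(),
                                 block_len_s = 300, filter_len = 5) {
  rows <- purrr::pmap(manifest, function(...) {
    row <- list(...)
    res <- tryCatch({
      track <- read_tracking(row$tracking_path)
      events <- read_events(row$events_path)
      speed <- compute_speed(track, filter_len)
      use <- filter(events, .data$kind == "real")
      if (nrow(use) == 0) use <- events
      ew <- event_windows(speed, use, spec, block_len_s = block_len_s)
      first_blk <- speed$v[speed$t < block_len_s]
      tibble(mouse_id = row$mouse_id,
             group = ifelse(row$group == "G1", 1, 0),
             session_idx = row$session_idx,
             v_pre = mean(ew$v_pre), v_post = mean(ew$v_post),
             delta = mean(ew$delta),
             v_firstblock = mean(first_blk, na.rm = TRUE))
    }, error = function(e) {
      warn(sprintf("session %s/%s excluded: %s",
                   row$mouse_id, row$session_idx, conditionMessage(e)))
      NULL
    })
    res
  })
  bind_rows(rows)
}

#' Fit the session-by-group speed regression
#'
#' Ordinary least squares of the pre-stimulation speed on session number,
#' group, and their interaction:
#' `speed = b0 + b1 * session + b2 * group + b3 * session * group`,
#' with session 1-based and uncentered, and group coded 1 for G1 and 0 for
#' G2. `b3` is the group-specific per-session slope: the long-term
#' facilitation of baseline speed attributable to repeated stimulation.
#'
#' @param table a long-term table from [build_longterm_table()] (or any
#'   tibble with `v_pre`, `session_idx`, `group`).
#' @param response column to regress (default `"v_pre"`).
#' @return `longterm_fit` object; see [tidy.longterm_fit()] and
#'   [glance.longterm_fit()].
#' @export
fit_longterm <- function(table, response = "v_pre") {
  if (length(unique(table$group)) < 2) {
    abort("both groups must be present: the group and interaction terms are unidentifiable")
  }
  df <- tibble(y = table[[response]], session = table$session_idx,
               group = table$group)
  df <- df[complete.cases(df), ]
  fit <- lm(y ~ session + group + session:group, data = df)
  if (anyNA(coef(fit))) abort("rank-deficient design: a session-by-group cell is empty")
  structure(list(fit = fit, response = response, n = nrow(df)),
            class = "longterm_fit")
}

#' @export
print.longterm_fit <- function(x, ...) {
  cat("Long-term session-by-group regression of", x$response, "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy / glance methods for long-term fits
#'
#' @param x a `longterm_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per coefficient (`beta0`..`beta3`) with
#'   estimate, standard error, t statistic, two-sided p-value and 95% CI.
#'   `glance()`: one-row model summary.
#' @export
tidy.longterm_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  ci <- confint(x$fit)
  tibble(term = c("beta0", "beta1", "beta2", "beta3"),
         role = c("intercept", "session", "group", "session_x_group"),
         estimate = unname(s[, 1]), std.error = unname(s[, 2]),
         statistic = unname(s[, 3]), p.value = unname(s[, 4]),
         conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]))
}

#' @rdname tidy.longterm_fit
#' @export
glance.longterm_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, nobs = x$n)
}

#' @export
predict.longterm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$fit))
  predict(object$fit, newdata = tibble(session = newdata$session_idx,
                                       group = newdata$group))
}

#' Early vs late session contrast
#'
#' Per-mouse means of a field over early and late session windows, compared
#' with a paired t test within each group. Mice missing either window are
#' excluded with a warning.
#'
#' @param table long-term table.
#' @param field column to contrast (e.g. `"v_pre"`, `"delta"`,
#'   `"v_firstblock"`).
#' @param early,late session index windows.
#' @return tibble per group: `group`, `n_mice`, `early_mean`, `late_mean`,
#'   `diff`, `statistic`, `p`.
#' @export
early_late_contrast <- function(table, field = "v_pre",
                                early = 1:6, late = 19:24) {
  per_mouse <- table %>%
    mutate(win = dplyr::case_when(.data$session_idx %in% early ~ "early",
                                  .data$session_idx %in% late ~ "late")) %>%
    filter(!is.na(.data$win)) %>%
    group_by(.data$mouse_id, .data$group, .data$win) %>%
    summarise(value = mean(.data[[field]], na.rm = TRUE), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "win", values_from = "value")
  incomplete <- is.na(per_mouse$early) | is.na(per_mouse$late)
  if (any(incomplete)) {
    warn(sprintf("excluding %d mice missing an early or late window", sum(incomplete)))
    per_mouse <- per_mouse[!incomplete, ]
  }
  per_mouse %>%
    group_by(.data$group) %>%
    dplyr::group_modify(function(df, key) {
      tr <- tryCatch(paired_compare(df$late, df$early),
                     error = function(e) test_result(NA_real_, NA_real_,
                                                     NA_real_, nrow(df)))
      tibble(n_mice = nrow(df), early_mean = mean(df$early),
             late_mean = mean(df$late), diff = mean(df$late - df$early),
             statistic = tr$statistic, p = tr$p)
    }) %>%
    ungroup()
}

slope_fit <- function(x, y) {
  # degenerate cases: a constant response carries no signal (R^2 = 0); a
  # constant predictor admits no slope estimate
  if (sd(y) == 0) return(tibble(slope = 0, r_squared = 0, p = 1, n_pairs = length(x)))
  if (sd(x) == 0) return(tibble(slope = NA_real_, r_squared = 0, p = 1, n_pairs = length(x)))
  fit <- lm(y ~ x)
  s <- summary(fit)
  tibble(slope = unname(coef(fit)[2]),
         r_squared = s$r.squared,
         p = s$coefficients[2, 4],
         n_pairs = length(x))
}

#' Short-term vs long-term coupling, procedure A
#'
#' Does a day's transient suppression predict the surrounding baseline
#' change? For every interior session n, the change in pre-stimulation
#' speed between the flanking sessions, `v_pre(n+1) - v_pre(n-1)`, is
#' regressed on the stimulation effect `delta(n)`; pairs are pooled across
#' mice (set `pool = FALSE` for per-mouse fits).
#'
#' @param table long-term table.
#' @param pool pool mouse-session pairs (default) or fit per mouse.
#' @return tibble `slope`, `r_squared`, `p`, `n_pairs` (plus `mouse_id` when
#'   `pool = FALSE`).
#' @export
short_long_correlation_A <- function(table, pool = TRUE) {
  pairs <- table %>%
    arrange(.data$mouse_id, .data$session_idx) %>%
    group_by(.data$mouse_id) %>%
    mutate(y = lead(.data$v_pre) - lag(.data$v_pre), x = .data$delta) %>%
    filter(!is.na(.data$y),
           lead(.data$session_idx) - .data$session_idx == 1,
           .data$session_idx - lag(.data$session_idx) == 1) %>%
    ungroup()
  if (nrow(pairs) < 3) abort("fewer than 3 usable session triplets")
  if (pool) slope_fit(pairs$x, pairs$y)
  else pairs %>% group_by(.data$mouse_id) %>%
    dplyr::group_modify(~ slope_fit(.x$x, .x$y)) %>% ungroup()
}

#' Short-term vs long-term coupling, procedure B
#'
#' Confound-avoiding variant: each mouse's pre-stimulation speeds are
#' detrended by a per-mouse linear fit against session, and the residual at
#' session n+1 is regressed on `delta(n)` (the last session of each mouse
#' contributes no pair).
#'
#' @inheritParams short_long_correlation_A
#' @export
short_long_correlation_B <- function(table, pool = TRUE) {
  pairs <- table %>%
    arrange(.data$mouse_id, .data$session_idx) %>%
    group_by(.data$mouse_id) %>%
    mutate(resid = residuals(lm(v_pre ~ session_idx,
                                data = dplyr::pick(dplyr::everything()))),
           y = lead(.data$resid), x = .data$delta) %>%
    filter(!is.na(.data$y),
           lead(.data$session_idx) - .data$session_idx == 1) %>%
    ungroup()
  if (nrow(pairs) < 3) abort("fewer than 3 usable session pairs")
  if (pool) slope_fit(pairs$x, pairs$y)
  else pairs %>% group_by(.data$mouse_id) %>%
    dplyr::group_modify(~ slope_fit(.x$x, .x$y)) %>% ungroup()
}
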