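#' Per-mouse peri-event speed summary
#'
#' Means of the pre-window speed, post-window speed and their difference
#' over the events of one mouse-session.
#'
#' @param event_stats output of [event_windows()].
#' @return one-row tibble `v_pre_mean`, `v_post_mean`, `delta`, `n_events`.
#' @export
mouse_delta <- function(event_stats) {
  if (nrow(event_stats) == 0) abort("need at least one event")
  tibble(v_pre_mean = mean(event_stats$v_pre),
         v_post_mean = mean(event_stats$v_post),
         delta = mean(event_stats$delta),
         n_events = nrow(event_stats))
}

#' Cohort peri-event summary
#'
#' Per-mouse statistics first, then unweighted averaging across mice with
#' SEM (the standard mean +/- SEM across animals).
#'
#' @param event_stats_by_mouse event stats tibble with a `mouse_id` column.
#' @return tibble `measure`, `mean`, `sem`, `n_mice`.
#' @export
cohort_delta <- function(event_stats_by_mouse) {
  per_mouse <- event_stats_by_mouse %>%
    group_by(.data$mouse_id) %>%
    summarise(v_pre_mean = mean(.data$v_pre), v_post_mean = mean(.data$v_post),
              delta = mean(.data$delta), .groups = "drop")
  per_mouse %>%
    tidyr::pivot_longer(-"mouse_id", names_to = "measure", values_to = "value") %>%
    group_by(.data$measure) %>%
    summarise(mean = mean(.data$value),
              sem = sd(.data$value) / sqrt(n()),
              n_mice = n(), .groups = "drop")
}

#' Normalized speed histogram
#'
#' @param v speeds, cm/s (NAs dropped).
#' @param bin_width_cms bin width, cm/s.
#' @return tibble `bin_lo`, `bin_mid`, `prob`; probabilities sum to 1.
#' @export
speed_distribution <- function(v, bin_width_cms = 1) {
  v <- v[!is.na(v)]
  if (length(v) == 0) abort("no speed samples")
  lo <- floor(v / bin_width_cms) * bin_width_cms
  tibble(bin_lo = lo) %>%
    dplyr::count(.data$bin_lo) %>%
    mutate(bin_mid = .data$bin_lo + bin_width_cms / 2,
           prob = .data$n / sum(.data$n)) %>%
    select(all_of(c("bin_lo", "bin_mid", "prob")))
}

# quartile cut points: linear interpolation between order statistics
# (quantile type 7), the rule used throughout the package
quartile_cuts <- function(v) quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)

assign_quartile <- function(v, cuts) {
  findInterval(v, cuts, left.open = TRUE) + 1L  # (-inf,c1] -> 1 ... (c3,inf) -> 4
}

#' Prior-speed quartile conditioning with sham correction
#'
#' Conditioning post-stimulation speed on the pre-stimulation speed induces
#' regression toward the mean even without any stimulation. The correction
#' subtracts, quartile by quartile, the same statistic computed on sham
#' events (equivalent within-block times in non-stimulated blocks): the
#' *delta-of-delta* `delta_real - delta_sham` is zero under the null in
#' every quartile and isolates the stimulation effect conditioned on prior
#' speed.
#'
#' Quartile cut points are computed per mouse from the pre-speed
#' distribution of that mouse's *real* events (linear interpolation between
#' order statistics); sham events are binned with the same cuts so real and
#' sham bins are comparable. Empty quartiles are reported with
#' `n_real`/`n_sham` of 0 and `NA` statistics.
#'
#' @param real_stats,sham_stats [event_windows()] outputs for real and sham
#'   events of one mouse (>= 4 events each).
#' @return `quartile_conditioning` tibble: `quartile`, `n_real`, `n_sham`,
#'   `pre_real`, `post_real`, `post_sham`, `delta_real`, `delta_sham`,
#'   `dod`; quartile cut points in `attr(, "cuts")`.
#' @export
quartile_conditioning <- function(real_stats, sham_stats) {
  if (nrow(real_stats) < 4 || nrow(sham_stats) < 4) {
    abort("need >= 4 real and >= 4 sham events")
  }
  cuts <- quartile_cuts(real_stats$v_pre)
  per_q <- function(stats) {
    stats %>%
      mutate(quartile = assign_quartile(.data$v_pre, cuts)) %>%
      group_by(.data$quartile) %>%
      summarise(n = n(), pre = mean(.data$v_pre), post = mean(.data$v_post),
                delta = mean(.data$delta), .groups = "drop")
  }
  grid <- tibble(quartile = 1:4)
  re <- left_join(grid, per_q(real_stats), by = "quartile")
  sh <- left_join(grid, per_q(sham_stats), by = "quartile")
  out <- tibble(
    quartile = 1:4,
    n_real = tidyr::replace_na(re$n, 0L),
    n_sham = tidyr::replace_na(sh$n, 0L),
    pre_real = re$pre, post_real = re$post, post_sham = sh$post,
    delta_real = re$delta, delta_sham = sh$delta,
    dod = re$delta - sh$delta
  )
  structure(out, cuts = cuts,
            class = c("quartile_conditioning", class(out)))
}

#' Cohort summary of quartile conditioning
#'
#' Averages per-mouse [quartile_conditioning()] results across mice
#' (unweighted, mean +/- SEM); mice with an empty quartile are excluded
#' from that quartile's mean and the exclusion count reported.
#'
#' @param results list of per-mouse `quartile_conditioning` tibbles.
#' @return tibble `quartile`, `dod_mean`, `dod_sem`, `delta_real_mean`,
#'   `delta_sham_mean`, `n_mice`, `n_excluded`.
#' @export
summarise_quartiles <- function(results) {
  bind_rows(results, .id = "mouse") %>%
    group_by(.data$quartile) %>%
    summarise(dod_mean = mean(.data$dod, na.rm = TRUE),
              dod_sem = sd(.data$dod, na.rm = TRUE) / sqrt(sum(!is.na(.data$dod))),
              delta_real_mean = mean(.data$delta_real, na.rm = TRUE),
              delta_sham_mean = mean(.data$delta_sham, na.rm = TRUE),
              n_mice = sum(!is.na(.data$dod)),
              n_excluded = sum(is.na(.data$dod)), .groups = "drop")
}

#' Dose-response of the stimulation effect
#'
#' Pearson correlation between stimulation pulse frequency and the per-mouse
#' delta speed at that frequency, pooled across mice.
#'
#' @param df tibble with columns `frequency` (Hz) and `delta` (cm/s).
#' @return one-row tibble `r`, `p`, `n` (see [pearson()]).
#' @export
dose_response <- function(df) {
  if (length(unique(df$frequency)) < 3) {
    abort("need >= 3 frequency levels for a dose-response")
  }
  res <- pearson(df$frequency, df$delta)
  tibble(r = res$statistic, p = res$p, n = res$n)
}
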