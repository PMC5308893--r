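#' Plot helpers
#'
#' ggplot2 views of the main result types: the tracked path over the zone
#' map, the event-aligned speed trace, the sham-corrected quartile
#' conditioning, ROI metrics across protocol sessions, and the long-term
#' regression.
#'
#' @name openfieldr-plots
NULL

#' @param object,x object to plot.
#' @param zonemap optional [zone_map()] to color the path by zone.
#' @param ... unused.
#' @rdname openfieldr-plots
#' @export
autoplot.of_tracking <- function(object, zonemap = NULL, ...) {
  df <- as_tibble(as.data.frame(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(zonemap)) {
    df$zone <- classify_zone(df$x, df$y, zonemap)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          color = .data$zone))
  }
  p + ggplot2::geom_path(linewidth = 0.2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
}

#' @param trace output of [peri_event_trace()] or [average_traces()].
#' @rdname openfieldr-plots
#' @export
plot_peri_event <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from stimulation onset (s)", y = "speed (cm/s)")
}

#' @rdname openfieldr-plots
#' @export
autoplot.quartile_conditioning <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            all_of(c("delta_real", "delta_sham", "dod")),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$quartile), y = .data$value,
                                   group = .data$measure,
                                   color = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "prior-speed quartile", y = "delta speed (cm/s)")
}

#' @param roi_summary output of [summarise_roi_cohort()].
#' @rdname openfieldr-plots
#' @export
plot_roi_cohort <- function(roi_summary) {
  ggplot2::ggplot(roi_summary,
                  ggplot2::aes(x = .data$session_label, y = .data$mean,
                               group = .data$genotype, color = .data$genotype)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "session", y = NULL)
}

#' @rdname openfieldr-plots
#' @export
autoplot.longterm_fit <- function(object, ...) {
  df <- object$fit$model
  df$pred <- predict(object$fit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session, y = .data$y,
                                   color = factor(.data$group))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred)) +
    ggplot2::labs(x = "session", y = object$response, color = "group (1 = G1)")
}
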