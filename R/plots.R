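#' Plot event-locked aggregate pupil curves
#'
#' Ribbon plot of the grand-average percent-change curves with +/- 1 SEM
#' bands per group.
#'
#' @param object A `"pupil_curves"` tibble from [aggregate_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pupil_curves
#' @export
autoplot.pupil_curves <- function(object, ...) {
  lock <- attr(object, "lock_event") %||% "event"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$t_lock, y = .data$mean_pct,
                               colour = .data$group_label,
                               fill = .data$group_label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                                      ymax = .data$mean_pct + .data$sem_pct),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("time from %s (s)", gsub("_", " ", lock)),
                  y = "pupil size change vs pre-trial baseline (%)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted time-by-valence pupil surface
#'
#' @param object A `"pupil_surface"` from [fit_response_surface()].
#' @param ... Unused.
#' @return A ggplot object (filled raster with contours).
#' @method autoplot pupil_surface
#' @export
autoplot.pupil_surface <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$t_lock,
                               y = .data$perceived_valence,
                               fill = .data$pct_fit)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$pct_fit),
                          colour = "white", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_viridis_c(name = "pupil change (%)") +
    ggplot2::labs(x = "time from response keypress (s)",
                  y = "perceived valence") +
    ggplot2::theme_minimal()
}

#' Plot fitted per-emotion valence ratings
#'
#' Point-interval plot of the fitted central valence per emotion
#' category and rating type from the mixed beta regression.
#'
#' @param x A `"pupil_rating_model"` from [fit_rating_model()].
#' @return A ggplot object.
#' @export
plot_ratings <- function(x) {
  ggplot2::ggplot(x$fitted,
                  ggplot2::aes(x = .data$emotion, y = .data$valence_fit,
                               colour = .data$valence_type)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "fitted valence (-50..+50)",
                  colour = "rating type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
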