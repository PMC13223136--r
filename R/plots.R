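# ggplot2 visualization methods for the result types.

#' Plot forecast trajectories with calibrated intervals
#'
#' @param object A forecast tibble from [forecast_episodes()].
#' @param episode_ids Episodes to display (default: first 4).
#' @param cytokine Marker to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctdose_forecast
#' @export
autoplot.ctdose_forecast <- function(object, episode_ids = NULL,
                                     cytokine = "il6", ...) {
  d <- object[object$cytokine == cytokine, ]
  if (is.null(episode_ids)) episode_ids <- utils::head(unique(d$episode_id), 4L)
  d <- d[d$episode_id %in% episode_ids, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$origin_h + .data$horizon_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo90, ymax = .data$hi90),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "steelblue") +
    ggplot2::facet_wrap(~episode_id, scales = "free_y") +
    ggplot2::labs(x = "hours since induction", y = paste(cytokine, "forecast"),
                  title = "Cytokine trajectory forecasts (90% intervals)") +
    ggplot2::theme_minimal()
}

#' Plot a dose-response partial-dependence curve
#'
#' @param object A `ctdose_pd` from [partial_dependence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctdose_pd
#' @export
autoplot.ctdose_pd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose, y = .data$predicted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo90, ymax = .data$hi90),
                         fill = "darkorange", alpha = 0.2) +
    ggplot2::geom_line(color = "darkorange", linewidth = 1) +
    ggplot2::facet_wrap(~cytokine, scales = "free_y") +
    ggplot2::labs(x = paste0(object$drug[1], " rate (mcg/kg/min)"),
                  y = "predicted 12-h level",
                  title = "Learned dose-response (cohort-median covariates)") +
    ggplot2::theme_minimal()
}

#' Plot the joint dose surface
#'
#' @param object A `ctdose_surface` from [dose_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctdose_surface
#' @export
autoplot.ctdose_surface <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$propofol, .data$ketamine)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$predicted)) +
    ggplot2::geom_point(data = object[object$argmin, ], shape = 8, size = 3,
                        color = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "propofol (mcg/kg/min)", y = "ketamine (mcg/kg/min)",
                  fill = "12-h IL-6", title = "Joint dose-response surface") +
    ggplot2::theme_minimal()
  pc <- attr(object, "policy_centroid")
  if (!is.null(pc)) {
    p <- p + ggplot2::annotate("point", x = pc[1], y = pc[2], shape = 23,
                               size = 4, fill = "gold")
  }
  p
}

#' Plot a Pareto frontier of the reward-weight sweep
#'
#' @param object Output of [pareto_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_pareto <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$il6_obj, y = .data$map_obj,
                                       color = .data$weight)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line(data = object[object$pareto, ][order(object$il6_obj[object$pareto]), ],
                       linetype = 2, color = "grey40") +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "mean IL-6 AUC (pg.h/mL, lower better)",
                  y = "% time MAP in 65-90 band (higher better)",
                  color = "MAP weight", title = "Reward-weight Pareto sweep") +
    ggplot2::theme_minimal()
}

#' Plot an attribution table
#'
#' @param object A `ctdose_attribution` from [attribution_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ctdose_attribution
#' @export
autoplot.ctdose_attribution <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"modality",
                              names_to = "target", values_to = "score")
  ord <- object$modality[order(object$composite)]
  long$modality <- factor(long$modality, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(.data$score, .data$modality,
                                     fill = .data$target)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "normalized attribution", y = NULL,
                  title = "Integrated-gradients attribution by modality") +
    ggplot2::theme_minimal()
}

#' Plot forecast calibration by horizon
#'
#' @param metrics Output of [forecast_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_coverage <- function(metrics, ...) {
  ggplot2::ggplot(metrics, ggplot2::aes(.data$horizon_h, .data$coverage90,
                                        color = .data$cytokine)) +
    ggplot2::geom_hline(yintercept = 0.9, linetype = 2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "horizon (h)", y = "empirical 90% coverage",
                  title = "Prediction-interval calibration") +
    ggplot2::theme_minimal()
}
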