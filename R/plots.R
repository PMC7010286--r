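#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_step geom_abline
#'   geom_boxplot labs facet_wrap annotate autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot model trajectories, optionally with observed data
#'
#' Draws the transient, persistent and residual components and their
#' total on a day grid; observed concentrations are overlaid as points
#' when a series is supplied.
#'
#' @param params An [sdnam_params] object.
#' @param series Optional data frame with `day` and `sdnam1_pm`.
#' @param t_max Right edge of the day grid (defaults to the last
#'   observation day, or 100).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(params, series = NULL, t_max = NULL) {
  params <- as_sdnam_params(params)
  if (is.null(t_max)) {
    t_max <- if (!is.null(series)) max(series$day, 10) else 100
  }
  traj <- solve_trajectories(params, seq(0, t_max, length.out = 400))
  long <- tidyr::pivot_longer(traj, c("x1", "x2", "x3", "total"),
                              names_to = "component", values_to = "pm")
  long$component <- factor(long$component,
                           levels = c("total", "x1", "x2", "x3"),
                           labels = c("total", "transient (x1)",
                                      "persistent (x2)", "residual (x3)"))
  p <- ggplot(long, aes(x = .data$time, y = .data$pm,
                        colour = .data$component)) +
    geom_line() +
    labs(x = "days after transplant", y = "sDNAM-1 (pM)", colour = NULL)
  if (!is.null(series)) {
    obs <- series[series$day >= 0, , drop = FALSE]
    p <- p + geom_point(data = obs,
                        aes(x = .data$day, y = .data$sdnam1_pm),
                        inherit.aes = FALSE, colour = "grey30")
  }
  p
}

#' @rdname fit_patient
#' @param object An `sdnam_fit` object.
#' @export
autoplot.sdnam_fit <- function(object, ...) {
  plot_trajectory(object$params, object$series)
}

#' @rdname roc_analysis
#' @param object An `sdnam_roc` object.
#' @export
autoplot.sdnam_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = 1 - .data$specificity,
                           y = .data$sensitivity)) +
    geom_step(direction = "vh") +
    geom_abline(linetype = "dotted", colour = "grey") +
    annotate("point", x = 1 - object$specificity, y = object$sensitivity,
             colour = "red") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("AUC = %.2f (%.2f-%.2f), cutoff %.3g",
                         object$auc, object$ci_low, object$ci_high,
                         object$cutoff))
}

#' Boxplots of R_day_n by GVHD status and horizon
#'
#' @param rday Tibble from [rday_cohort] (columns `patient_id`, `day_n`,
#'   `r_day_n`).
#' @param metadata Metadata tibble with `patient_id` and `gvhd_status`.
#' @return A ggplot object, one panel per horizon.
#' @export
plot_rday_groups <- function(rday, metadata) {
  d <- dplyr::inner_join(rday, metadata[c("patient_id", "gvhd_status")],
                         by = "patient_id")
  d$group <- ifelse(d$gvhd_status, "GVHD (+)", "GVHD (-)")
  ggplot(d, aes(x = .data$group, y = .data$r_day_n)) +
    geom_boxplot() +
    facet_wrap(~day_n, nrow = 1,
               labeller = ggplot2::labeller(
                 day_n = function(v) paste0("R_day_", v))) +
    labs(x = NULL, y = "R_day_n (%)")
}
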