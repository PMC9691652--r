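#' Plot a cohort trace as stacked state occupancy
#'
#' @param object A `cea_trace` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cea_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), dplyr::all_of(STATES),
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = STATES,
                       labels = c("NYHA I", "NYHA II", "NYHA III", "NYHA IV", "Dead"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (months)", y = "State occupancy", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars span the ICER at each parameter's low and high bound,
#' ranked by swing, with a vertical line at the base-case ICER.
#'
#' @param object A `cea_tornado` from [one_way_sensitivity()].
#' @param top Show only the `top` largest swings (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cea_tornado <- function(object, top = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(top)) df <- utils::head(df, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base_icer <- attr(object, "base_icer")
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (CNY/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatter of PSA draws
#'
#' One point per Monte Carlo draw on the incremental-effectiveness /
#' incremental-cost plane, with the willingness-to-pay threshold drawn as a
#' line through the origin.
#'
#' @param object A `cea_psa` from [run_psa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cea_psa <- function(object, ...) {
  wtp <- attr(object, "wtp")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = 2) +
    ggplot2::labs(x = "Incremental effectiveness (QALY)",
                  y = "Incremental cost (CNY)") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `cea_ceac` from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cea_ceac <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("acceptability", "acceptability_comparator"),
                            names_to = "strategy", values_to = "probability")
  df$strategy <- ifelse(df$strategy == "acceptability", "MitraClip", "OMT")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (CNY/QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}
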