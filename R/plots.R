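#' Bar chart of survival times by organism and scenario
#'
#' Mirrors the usual survivability layout: organisms on the x axis, years on
#' a log10 y axis, one bar per scenario. Infinite ("never inactivated")
#' times are dropped with a message.
#'
#' @param table Output of [survival_table()].
#' @return A ggplot object.
#' @examples
#' plot_survival_times(survival_table(reference_thresholds(),
#'                                    reference_scenarios()))
#' @export
plot_survival_times <- function(table) {
  check_columns(table, c("organism", "scenario", "time_to_inactivation_yr"),
                "table")
  finite <- filter(table, is.finite(.data$time_to_inactivation_yr))
  if (nrow(finite) < nrow(table)) {
    inform("Dropping zero-rate scenarios with no finite inactivation time.")
  }
  ggplot2::ggplot(finite,
                  ggplot2::aes(x = .data$organism,
                               y = .data$time_to_inactivation_yr,
                               fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10(labels = function(x)
      format(x, big.mark = " ", scientific = FALSE, trim = TRUE)) +
    ggplot2::labs(x = NULL, y = "Time to inactivation (yr)",
                  fill = "Scenario",
                  caption = "Dormant, non-repairing populations") +
    ggplot2::theme_minimal()
}

#' Heatmap of module presence calls
#'
#' @param presence Long tibble `(genome_id or genus, module_id, present)`
#'   from [call_presence()] or [genus_aggregate()].
#' @return A ggplot object.
#' @export
plot_presence_matrix <- function(presence) {
  check_columns(presence, c("module_id", "present"), "presence")
  row_var <- if ("genome_id" %in% names(presence)) "genome_id" else "genus"
  ggplot2::ggplot(presence,
                  ggplot2::aes(x = .data$module_id, y = .data[[row_var]],
                               fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::labs(x = "Module", y = NULL, fill = "Present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Bar chart of family-level composition
#'
#' @param composition Output of [family_composition()].
#' @return A ggplot object.
#' @export
plot_family_composition <- function(composition) {
  check_columns(composition, c("family", "percent"), "composition")
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = stats::reorder(.data$family, .data$percent),
                               y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative abundance (%)") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot for a log-linear inactivation fit
#'
#' Points are the observed curve on a log10 survival scale; the line is the
#' fitted single-hit model.
#'
#' @param object A `survival_fit` from [fit_loglinear()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_fit <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dose_gy,
                                    y = log10(.data$surviving_fraction))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "Dose (Gy)", y = "log10 surviving fraction",
      title = if (!is.na(object$organism)) object$organism else NULL,
      subtitle = sprintf("D10 = %.5g Gy, R² = %.3f",
                         object$d10_gy, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
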