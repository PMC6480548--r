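# ggplot2 views mirroring the dashboard: unit cost vs volume quadrants,
# quarterly trends, and the facility comparison bar.

#' Plot a cost-volume view
#'
#' Scatter of unit expenditure against output volume with the group medians
#' drawn as quadrant boundaries, so high-volume/high-cost exceptions stand
#' out.
#'
#' @param object A `rems_cost_volume` from [cost_volume_view()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.rems_cost_volume <- function(object, ...) {
  med <- attr(object, "medians")
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$volume, y = .data$unit_total)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$quadrant), size = 2) +
    ggplot2::labs(
      x = "Output volume (visits/quarter)",
      y = "Unit expenditure (Kwacha/visit)",
      title = sprintf("Unit expenditure vs volume: %s, %s",
                      attr(object, "service") %||% "",
                      attr(object, "period") %||% ""),
      colour = "Quadrant"
    )
  if (!is.null(med)) {
    p <- p +
      ggplot2::geom_vline(xintercept = med[["volume"]], linetype = "dashed") +
      ggplot2::geom_hline(yintercept = med[["unit_total"]], linetype = "dashed")
  }
  p
}

#' Plot unit-expenditure trends
#'
#' One line per facility, faceted by service, over calendar quarters.
#'
#' @param object A `rems_trend` from [trend()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.rems_trend <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(period = quarter_label(.data$year, .data$quarter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$unit_total,
                                   group = .data$facility,
                                   colour = .data$facility)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$service), scales = "free_y") +
    ggplot2::labs(x = "Quarter", y = "Unit expenditure (Kwacha/visit)",
                  colour = "Facility")
}

#' Facility comparison bar chart
#'
#' Unit expenditure per facility for one service and quarter, ordered
#' descending, optionally stacked by resource category.
#'
#' @param units Tibble from [compute_unit_expenditure()].
#' @param service Service code.
#' @param year,quarter Period.
#' @param by_category Stack bars by resource category (uses the
#'   `unit_<category>` columns).
#' @return A ggplot.
#' @export
plot_facility_comparison <- function(units, service, year, quarter,
                                     by_category = FALSE) {
  df <- units %>%
    filter(.data$status == "ok", .data$service == !!service,
           .data$year == !!year, .data$quarter == !!quarter)
  if (by_category) {
    long <- df %>%
      select("facility", "unit_total", dplyr::starts_with("unit_")) %>%
      tidyr::pivot_longer(cols = dplyr::starts_with("unit_") &
                            !dplyr::matches("^unit_total$"),
                          names_to = "resource_category",
                          names_prefix = "unit_", values_to = "unit_amount")
    ggplot2::ggplot(long, ggplot2::aes(
      x = stats::reorder(.data$facility, -.data$unit_total),
      y = .data$unit_amount, fill = .data$resource_category)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "Facility", y = "Unit expenditure (Kwacha/visit)",
                    fill = "Resource category",
                    title = sprintf("%s, %s", service,
                                    quarter_label(year, quarter))) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(
      x = stats::reorder(.data$facility, -.data$unit_total),
      y = .data$unit_total)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "Facility", y = "Unit expenditure (Kwacha/visit)",
                    title = sprintf("%s, %s", service,
                                    quarter_label(year, quarter))) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
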