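# ggplot2 views of the main result objects

#' Cost-effectiveness plane
#'
#' Scatter of incremental cost against incremental QALYs per PSA draw for
#' each comparator against a reference strategy.
#'
#' @param psa A `psa_result`.
#' @param ref Reference strategy label.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, ref = "surveillance") {
  res <- psa$results
  refd <- dplyr::filter(res, .data$strategy == ref)
  comp <- dplyr::filter(res, .data$strategy != ref) |>
    dplyr::left_join(refd, by = "draw", suffix = c("", "_ref")) |>
    dplyr::mutate(inc_cost = .data$cost - .data$cost_ref,
                  inc_qaly = .data$qaly - .data$qaly_ref)
  ggplot2::ggplot(comp, ggplot2::aes(.data$inc_qaly, .data$inc_cost,
                                     colour = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                  colour = NULL,
                  title = paste("Cost-effectiveness plane vs", ref)) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param x A `psa_result` or a CEAC tibble from [ceac()].
#' @param wtp_grid Willingness-to-pay grid (used when `x` is a `psa_result`).
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, wtp_grid = seq(0, 50000, by = 1000)) {
  curve <- if (inherits(x, "psa_result")) ceac(x, wtp_grid) else x
  ggplot2::ggplot(curve, ggplot2::aes(.data$wtp, .data$probability,
                                      colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay per QALY (GBP)",
                  y = "P(most cost-effective)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Expected value of perfect information curve
#'
#' @param evpi_tbl Tibble with columns `wtp` and one of `evpi_population` /
#'   `evpi_per_person`.
#' @return A ggplot object.
#' @export
plot_evpi <- function(evpi_tbl) {
  ycol <- if ("evpi_population" %in% names(evpi_tbl)) "evpi_population" else "evpi_per_person"
  ggplot2::ggplot(evpi_tbl, ggplot2::aes(.data$wtp, .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness-to-pay per QALY (GBP)",
                  y = if (ycol == "evpi_population") "Population EVPI (GBP)" else "EVPI per person (GBP)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ce_plane
#' @param object A `psa_result`.
#' @param ... Unused.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) plot_ce_plane(object)

#' State occupancy over time
#'
#' @param object An `ipn_trace`.
#' @param ... Unused.
#' @return A ggplot object showing occupancy by state group over cohort age.
#' @method autoplot ipn_trace
#' @export
autoplot.ipn_trace <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::summarise(occupancy = sum(.data$occupancy),
                     .by = c("time", "age", "group"))
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$occupancy,
                                   fill = .data$group)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cohort age (years)", y = "Occupancy", fill = NULL) +
    ggplot2::theme_minimal()
}
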