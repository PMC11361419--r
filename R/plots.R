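#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: rank maps
#' and delta-rank maps as raster tiles (protected cells in green),
#' transition summaries as grouped bars, importance profiles as ordered
#' bars, partial-dependence curves as lines, and protection records as
#' per-status boxplots.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name riskfill-autoplot
NULL

#' @rdname riskfill-autoplot
#' @export
autoplot.rank_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$rank)) +
    ggplot2::geom_raster(data = dplyr::filter(object, .data$protected),
                         fill = "darkgreen") +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "priority\nrank", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname riskfill-autoplot
#' @export
autoplot.delta_rank_map <- function(object, ...) {
  lim <- max(abs(object$delta), na.rm = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$delta)) +
    ggplot2::geom_raster(data = dplyr::filter(object, .data$protected),
                         fill = "darkgreen") +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  limits = c(-lim, lim)) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "delta\nrank", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname riskfill-autoplot
#' @export
autoplot.transition_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("n_before", "n_after"),
                              names_to = "when", values_to = "n") |>
    dplyr::mutate(when = factor(sub("n_", "", .data$when),
                                levels = c("before", "after")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$status, y = .data$n,
                                     fill = .data$when)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(before = "grey65", after = "grey25")) +
    ggplot2::labs(x = NULL, y = "species", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname riskfill-autoplot
#' @export
autoplot.importance_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$feature, .data$importance_pct),
                               y = .data$importance_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative importance (%)") +
    ggplot2::theme_minimal()
}

#' @rdname riskfill-autoplot
#' @export
autoplot.partial_curve <- function(object, ...) {
  if (is.numeric(object$value)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$p_threat)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = unique(object$feature), y = "P(Threatened)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$p_threat)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = unique(object$feature), y = "P(Threatened)") +
      ggplot2::theme_minimal()
  }
}

#' @rdname riskfill-autoplot
#' @export
autoplot.protection_record <- function(object, ...) {
  if (!"status" %in% names(object)) {
    abort("Join a status column before plotting protection records.")
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("coverage", "achievement"),
                              names_to = "metric", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$status, y = .data$pct,
                                     fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "%") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
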