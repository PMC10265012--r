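# ggplot2 views of the pipeline's result types.

#' Plot an accumulation curve
#'
#' Expected parasite richness against the number of sampled host species; a
#' ribbon of +/- one Monte-Carlo standard deviation is added when the curve
#' carries a variance column.
#'
#' @param object An `accumulation_curve` from [accumulation_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accumulation_curve
#' @export
autoplot.accumulation_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$expected)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "host species sampled",
                  y = "expected parasite richness") +
    ggplot2::theme_minimal()
  if ("variance" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$expected - sqrt(.data$variance),
                   ymax = .data$expected + sqrt(.data$variance)),
      alpha = 0.2)
  }
  p
}

#' Plot per-ecosystem accumulation curves from a pipeline run
#'
#' @param curves The `accumulation` tibble of [run_full_pipeline()] (columns
#'   `k`, `expected`, `ecosystem`, `partition`).
#' @return A ggplot object, one panel per host partition.
#' @export
plot_accumulation <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$k, y = .data$expected,
                                       colour = .data$ecosystem)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~partition, scales = "free") +
    ggplot2::labs(x = "host species sampled",
                  y = "expected parasite richness", colour = "ecosystem") +
    ggplot2::theme_minimal()
}

#' Plot a composition table
#'
#' Stacked proportional bars of morphogroup counts per ecosystem, by
#' life-cycle or life-stage category.
#'
#' @param object A `contingency_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contingency_table
#' @export
autoplot.contingency_table <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("category", "ecosystem", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ecosystem, y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(y = "proportion of morphogroups", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot mean within-host-species richness by ecosystem and host group
#'
#' Mean +/- one standard error of the per-host-species Chao2 estimates, with
#' the number of host species annotated above each bar.
#'
#' @param summaries A tibble from [host_species_summaries()].
#' @return A ggplot object.
#' @export
plot_richness_summary <- function(summaries) {
  agg <- summaries |>
    dplyr::group_by(.data$ecosystem, .data$host_group) |>
    dplyr::summarise(mean = mean(.data$chao2_estimate),
                     se = stats::sd(.data$chao2_estimate) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$ecosystem, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + .data$se, label = .data$n),
                       vjust = -0.5, size = 3) +
    ggplot2::facet_wrap(~host_group) +
    ggplot2::labs(x = NULL, y = "Chao2 richness within host species") +
    ggplot2::theme_minimal()
}
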