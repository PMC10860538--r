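#' Fishplot-style clone-fraction chart for one or more patients
#'
#' Stacked-area rendition of clone fractions across the two timepoints,
#' faceted by patient — the data layer of a fishplot.
#'
#' @param fish tibble from [fishplot_table()] (or the pipeline's
#'   `fishplot` table): `patient_id`, `clone_id`, `timepoint`, `fraction`
#' @param include_wt include the WT clone band (FALSE)
#' @return a ggplot object
#' @export
plot_fishplot <- function(fish, include_wt = FALSE) {
  df <- fish
  if (!include_wt) df <- dplyr::filter(df, .data$clone_id != "WT")
  df$timepoint <- factor(df$timepoint, levels = TIMEPOINT_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = as.integer(.data$timepoint),
                                   y = .data$fraction,
                                   fill = .data$clone_id)) +
    ggplot2::geom_area(position = "stack", alpha = 0.85) +
    ggplot2::scale_x_continuous(breaks = 1:2, labels = TIMEPOINT_LEVELS) +
    ggplot2::facet_wrap(~patient_id) +
    ggplot2::labs(x = NULL, y = "fraction of cells", fill = "clone") +
    ggplot2::theme_minimal()
}

#' @rdname composition_test
#' @param object a `composition_test`
#' @method autoplot composition_test
#' @export
autoplot.composition_test <- function(object, ...) {
  df <- object$result
  df$population <- stats::reorder(df$population, df$effect)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$population,
                                   fill = .data$credible)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "log fold change (reference ratio)", y = NULL,
                  fill = sprintf("credible (FDR %.2f)", object$fdr)) +
    ggplot2::theme_minimal()
}

#' Region-level ploidy heatmap
#'
#' @param pt a [compute_ploidy()] result
#' @return a ggplot object
#' @export
plot_ploidy <- function(pt) {
  ggplot2::ggplot(pt$region_calls,
                  ggplot2::aes(x = .data$region, y = .data$clone_id,
                               fill = .data$median_ploidy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 2, low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  limits = c(0, 4)) +
    ggplot2::labs(x = "region", y = "clone", fill = "ploidy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
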