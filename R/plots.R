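#' Stacked-bar plot of state-transition proportions
#'
#' One bar per starting state, filled by the destination state's share —
#' the standard view of how promoter chromatin states redistribute between
#' conditions. Faceted by CpG class when the table was stratified.
#'
#' @param object A [transition_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transition_table
#' @export
autoplot.transition_table <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$proportion), ]
  d$state_from <- factor(d$state_from, levels = .PS_STATES)
  d$state_to <- factor(d$state_to, levels = .PS_STATES)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$state_from,
                                       y = .data$proportion,
                                       fill = .data$state_to)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = paste("state in", object$from),
                  y = paste("proportion of states in", object$to),
                  fill = "state") +
    ggplot2::theme_minimal()
  if (length(unique(d$cpg_class)) > 1) {
    p <- p + ggplot2::facet_wrap(~cpg_class)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot of expression by chromatin state
#'
#' @param expression_by_state Tibble `condition`, `state`, `fpkm` (e.g. the
#'   `expression_by_state` element of a [run_pipeline()] result).
#' @param log_scale Plot `log10(FPKM + 1)` (default TRUE).
#' @return A ggplot object.
#' @export
plot_state_expression <- function(expression_by_state, log_scale = TRUE) {
  d <- expression_by_state
  d$value <- if (log_scale) log10(d$fpkm + 1) else d$fpkm
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$state, levels = .PS_STATES),
                                  y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "promoter chromatin state",
                  y = if (log_scale) "log10(FPKM + 1)" else "FPKM") +
    ggplot2::theme_minimal()
}

#' Scatter plot of promoter occupancy against expression
#'
#' Log-log scatter with the Spearman rho in the subtitle.
#'
#' @param occupancy Long occupancy tibble (one mark/condition is selected).
#' @param expression Expression tibble (`gene_id`, `fpkm_NR`, `fpkm_R`).
#' @param mark,condition Which occupancy column to plot.
#' @param fpkm_column Which expression column pairs with `condition`.
#' @return A ggplot object.
#' @export
plot_occupancy_expression <- function(occupancy, expression, mark, condition,
                                      fpkm_column = "fpkm_NR") {
  occ <- occupancy[occupancy$mark == mark &
                     occupancy$condition == condition, ]
  fpkm <- expression[[fpkm_column]][match(occ$gene_id, expression$gene_id)]
  rho <- spearman_occupancy_expression(occ$occupancy, fpkm)
  ggplot2::ggplot(tibble::tibble(occ = occ$occupancy + 1, fpkm = fpkm + 1),
                  ggplot2::aes(x = .data$occ, y = .data$fpkm)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste(mark, "promoter occupancy + 1"),
                  y = "FPKM + 1",
                  title = paste(mark, "in", condition),
                  subtitle = sprintf("Spearman rho = %.2f", rho)) +
    ggplot2::theme_minimal()
}

#' Metagene line plot of gene-body coverage
#'
#' @param profile Tibble from [genebody_coverage_profile()] (optionally with
#'   a `condition` column for faceting).
#' @return A ggplot object.
#' @export
plot_genebody_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin,
                                             y = .data$mean_coverage,
                                             colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gene-body bin (5' to 3')",
                  y = "mean coverage (tags per million)",
                  colour = "group") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(profile)) p <- p + ggplot2::facet_wrap(~condition)
  p
}
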