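#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_step geom_tile
#'   geom_hline geom_vline geom_text geom_errorbarh labs scale_fill_gradient2
#'   theme_minimal
NULL

#' Volcano plot of per-dataset correlations
#'
#' Correlation coefficient against -log10 p per dataset, with the
#' significance boundaries drawn and points coloured by classification.
#'
#' @param object A [volcano_classify()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.volcano_summary <- function(object, ...) {
  rt <- attr(object, "r_threshold")
  pt <- attr(object, "p_threshold")
  ggplot(object, aes(x = .data$rho, y = -log10(.data$p_value),
                     colour = .data$direction)) +
    geom_point() +
    geom_vline(xintercept = c(-rt, rt), linetype = "dashed") +
    geom_hline(yintercept = -log10(pt), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(positive = "#c0392b",
                                            negative = "#2980b9",
                                            ns = "grey60")) +
    labs(x = sprintf("%s vs %s correlation (R)",
                     object$metric_x[1], object$metric_y[1]),
         y = expression(-log[10](p)), colour = NULL) +
    theme_minimal()
}

#' Kaplan-Meier step curves
#'
#' @param object A [kaplan_meier()] result.
#' @param ... Unused.
#' @return A ggplot of per-group survival curves annotated with the
#'   log-rank p-value.
#' @export
autoplot.km_result <- function(object, ...) {
  steps <- tidy(object) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, estimate = 1), .x[, c("time", "estimate")])) |>
    dplyr::ungroup()
  ggplot(steps, aes(x = .data$time, y = .data$estimate, colour = .data$group)) +
    geom_step() +
    labs(x = "time", y = "overall survival probability", colour = NULL,
         subtitle = sprintf("log-rank p = %.3g", object$logrank_p)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    theme_minimal()
}

#' Checkpoint-gene x hallmark correlation heatmap
#'
#' Spearman rho as a filled tile per (gene, signature) cell;
#' insignificant cells are marked with an "X", following the published
#' heatmap convention.
#'
#' @param object A [checkpoint_hallmark_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.checkpoint_table <- function(object, ...) {
  ggplot(object, aes(x = .data$metric, y = .data$gene, fill = .data$rho)) +
    geom_tile() +
    geom_text(data = dplyr::filter(object, !.data$significant),
              aes(label = "X"), inherit.aes = TRUE) +
    scale_fill_gradient2(low = "#2980b9", mid = "white", high = "#c0392b",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman R") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Forest plot of log2 hazard ratios
#'
#' @param forest Tibble with columns `label`, `log2_hr`, `ci_low`,
#'   `ci_high` (hazard-ratio scale CIs), e.g. rows of
#'   [tidy.cox_result()] across cohorts with a `label` column added.
#' @return A ggplot with log2 HR points, CI bars and the null line at 0.
#' @export
plot_forest <- function(forest) {
  ggplot(forest, aes(x = .data$log2_hr, y = .data$label)) +
    geom_point() +
    geom_errorbarh(aes(xmin = log2(.data$ci_low), xmax = log2(.data$ci_high)),
                   height = 0.2) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = expression(log[2] ~ "hazard ratio"), y = NULL) +
    theme_minimal()
}
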