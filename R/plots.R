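#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_curves` tibble from [km_curve()].
#' @param ... Unused.
#' @return A ggplot: step survival curves per group.
#' @export
autoplot.km_curves <- function(object, ...) {
  # prepend the (0, 1) anchor per group so curves start at S = 1
  anchors <- object %>%
    dplyr::group_by(.data$group) %>%
    dplyr::slice(1) %>%
    dplyr::mutate(time = 0, survival = 1) %>%
    dplyr::ungroup()
  dplyr::bind_rows(anchors, object) %>%
    ggplot(aes(x = .data$time, y = .data$survival, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of a meta co-expression result
#'
#' @param object A `meta_coexpr_result`.
#' @param ... Unused.
#' @return A ggplot: per-dataset logit effect sizes with intervals and the
#'   pooled summary.
#' @export
autoplot.meta_coexpr_result <- function(object, ...) {
  tab <- forest_table(object) %>%
    dplyr::mutate(label = factor(.data$label, levels = rev(.data$label)))
  ggplot(tab, aes(x = .data$es, y = .data$label, colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(aes(shape = .data$kind), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(dataset = "grey30",
                                            summary = "firebrick")) +
    ggplot2::labs(x = "effect size  ln(p / (1 - p))", y = NULL,
                  title = object$pathway) +
    ggplot2::guides(colour = "none", shape = "none") +
    ggplot2::theme_minimal()
}

#' Paired tumor/normal pathway-mean plot
#'
#' Violin distributions per tissue with line segments connecting each
#' subject's paired means.
#'
#' @param object A `pathway_patient_means` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathway_patient_means <- function(object, ...) {
  long <- object %>%
    tidyr::pivot_longer(c("tumor_mean", "normal_mean"),
                        names_to = "tissue", values_to = "mean_expr") %>%
    dplyr::mutate(tissue = sub("_mean$", "", .data$tissue))
  ggplot(long, aes(x = .data$tissue, y = .data$mean_expr)) +
    ggplot2::geom_violin(aes(fill = .data$tissue), alpha = 0.4) +
    ggplot2::geom_line(aes(group = .data$subject_id), alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = "mean log2 expression",
                  title = attr(object, "pathway")) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Heatmap of a clustered adjusted-p-value matrix
#'
#' @param object A `pvalue_clustering` from [cluster_pvalue_matrix()].
#' @param ... Unused.
#' @return A ggplot tile heatmap in dendrogram leaf order.
#' @export
autoplot.pvalue_clustering <- function(object, ...) {
  m <- object$matrix
  long <- as_tibble(m, rownames = "cancer") %>%
    tidyr::pivot_longer(-"cancer", names_to = "pathway",
                        values_to = "adj_p") %>%
    dplyr::mutate(
      cancer = factor(.data$cancer, levels = object$row_order),
      pathway = factor(.data$pathway, levels = object$col_order)
    )
  ggplot(long, aes(x = .data$pathway, y = .data$cancer, fill = .data$adj_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "firebrick", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "adj. p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
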