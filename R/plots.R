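# ggplot2 autoplot methods for the main result types.

#' Plot a soft-threshold sweep
#'
#' Scale-free fit (signed R^2) against candidate power, with the target fit
#' and the chosen power highlighted.
#'
#' @param object A `soft_threshold_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot soft_threshold_fit
#' @export
autoplot.soft_threshold_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$power, y = .data$fit)) +
    ggplot2::geom_hline(yintercept = object$target_fit, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "soft-threshold power", y = expression(signed~R^2),
                  title = "Scale-free topology fit") +
    ggplot2::theme_minimal()
}

#' Plot a co-expression null distribution
#'
#' Histogram of metabolic-pair correlations with the percentile threshold.
#'
#' @param object A `pcc_null`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcc_null
#' @export
autoplot.pcc_null <- function(object, bins = 60, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "red") +
    ggplot2::labs(x = "pairwise Pearson r",
                  y = "pairs",
                  title = sprintf("Metabolic-pair null (threshold %.3f, %sth percentile)",
                                  object$threshold, fmt_num(object$percentile))) +
    ggplot2::theme_minimal()
}

#' Heatmap of module-trait correlations
#'
#' Modules by traits, tile colour = r, significant cells starred.
#'
#' @param object A `module_trait_cor`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot module_trait_cor
#' @export
autoplot.module_trait_cor <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant, "*", "")),
                       size = 5) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "BGC trait", y = "module",
                  title = "Module eigengene vs BGC trait correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot module eigengene profiles
#'
#' One line per module eigengene across samples.
#'
#' @param object A `module_set` with eigengenes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot module_set
#' @export
autoplot.module_set <- function(object, ...) {
  if (is.null(object$eigengenes)) abort("module_set has no eigengenes")
  df <- tibble::as_tibble(object$eigengenes, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "module", values_to = "eigengene")
  df$sample_id <- factor(df$sample_id, levels = rownames(object$eigengenes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$eigengene,
                                   colour = .data$module,
                                   group = .data$module)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "eigengene", title = "Module eigengene profiles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a regulator-cluster co-expression matrix
#'
#' @param object A `regulator_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot regulator_matrix
#' @export
autoplot.regulator_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster_gene, y = .data$regulator,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "cluster gene", y = "candidate regulator",
                  title = "Regulator-cluster co-expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
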