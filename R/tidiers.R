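# broom-style tidiers for the package's result objects.

#' Tidy a module set
#'
#' @param x A `module_set`.
#' @param ... Unused.
#' @return Tibble with `gene_id` and `module` (the reserved label
#'   `"unassigned"` marks genes outside every module).
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  dplyr::arrange(x$assignment, .data$gene_id)
}

#' One-row summary of a module set
#'
#' @param x A `module_set`.
#' @param ... Unused.
#' @return Tibble: module count, gene counts, size range, soft-threshold
#'   power and mean explained variance.
#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  sizes <- table(x$assignment$module[x$assignment$module != "unassigned"])
  tibble(
    n_modules = length(sizes),
    n_genes = nrow(x$assignment),
    n_unassigned = sum(x$assignment$module == "unassigned"),
    min_size = if (length(sizes)) as.integer(min(sizes)) else NA_integer_,
    max_size = if (length(sizes)) as.integer(max(sizes)) else NA_integer_,
    power = x$power %||% NA_integer_,
    mean_var_explained = if (!is.null(x$var_explained)) mean(x$var_explained) else NA_real_
  )
}

#' Tidy module-trait correlations
#'
#' @param x A `module_trait_cor`.
#' @param ... Unused.
#' @return Long tibble: `module`, `trait`, `r`, `p`, `significant`.
#' @method tidy module_trait_cor
#' @export
tidy.module_trait_cor <- function(x, ...) {
  out <- tibble(
    module = rep(rownames(x$r), times = ncol(x$r)),
    trait = rep(colnames(x$r), each = nrow(x$r)),
    r = as.vector(x$r),
    p = as.vector(x$p),
    significant = as.vector(x$significant)
  )
  dplyr::arrange(out, .data$module, .data$trait)
}

#' @method glance module_trait_cor
#' @export
glance.module_trait_cor <- function(x, ...) {
  tibble(n_modules = nrow(x$r), n_traits = ncol(x$r),
         n_significant = sum(x$significant), n_samples = x$n)
}

#' Tidy a co-expression null
#'
#' @param x A `pcc_null`.
#' @param ... Unused.
#' @return Tibble of the scored pair correlations.
#' @method tidy pcc_null
#' @export
tidy.pcc_null <- function(x, ...) {
  tibble(r = x$r_values)
}

#' @method glance pcc_null
#' @export
glance.pcc_null <- function(x, ...) {
  tibble(threshold = x$threshold, percentile = x$percentile,
         n_pairs_sampled = x$n_pairs_sampled, absolute = x$absolute)
}

#' Tidy a soft-threshold sweep
#'
#' @param x A `soft_threshold_fit`.
#' @param ... Unused.
#' @return The fit table with a `chosen` flag.
#' @method tidy soft_threshold_fit
#' @export
tidy.soft_threshold_fit <- function(x, ...) {
  dplyr::mutate(x$table, chosen = .data$power == x$power)
}

#' Tidy a regulator-cluster matrix
#'
#' @param x A `regulator_matrix`.
#' @param ... Unused.
#' @return Long tibble: `regulator`, `cluster_gene`, `r`, `p`.
#' @method tidy regulator_matrix
#' @export
tidy.regulator_matrix <- function(x, ...) {
  tibble(
    regulator = rep(rownames(x$r), times = ncol(x$r)),
    cluster_gene = rep(colnames(x$r), each = nrow(x$r)),
    r = as.vector(x$r),
    p = as.vector(x$p)
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `run_summary`.
#' @param ... Unused.
#' @return Tibble with funnel counts, module statistics, hub count and (when
#'   a ledger was scored) recovery metrics.
#' @method glance run_summary
#' @export
glance.run_summary <- function(x, ...) {
  tibble(
    scanned = x$funnel$scanned,
    copathway_pass = x$funnel$copathway,
    validated = x$funnel$validated,
    n_modules = x$n_modules,
    n_hubs = x$n_hubs,
    n_significant_cells = x$n_significant_cells,
    cluster_precision = x$scores$cluster_precision %||% NA_real_,
    cluster_recall = x$scores$cluster_recall %||% NA_real_,
    module_ari = x$scores$module_ari %||% NA_real_,
    hub_recall = x$scores$hub_recall %||% NA_real_
  )
}

#' Tidy an expression matrix into long form
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return Long tibble `gene_id`, `sample_id`, `value` joined with sample
#'   metadata.
#' @method tidy expr_matrix
#' @export
tidy.expr_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "value")
  dplyr::left_join(long, x$samples, by = "sample_id")
}
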