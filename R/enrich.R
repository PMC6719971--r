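#' Hypergeometric term enrichment for a module
#'
#' For every annotation term with at least one module gene, the upper-tail
#' hypergeometric probability of observing at least the seen overlap is
#' computed (sampling `n_module` genes from a universe of `n_universe`, of
#' which `n_term_universe` carry the term), followed by Benjamini-Hochberg
#' correction across the tested terms. Rows passing both `p < p_max` and
#' `fdr < fdr_max` (defaults 1e-4 and 0.05) are returned, sorted by p.
#'
#' @param module_genes Character vector of module gene ids (must be a subset
#'   of `universe`).
#' @param universe All scoreable gene ids.
#' @param terms Tibble mapping `gene_id` to `term_id` (optional `term_name`);
#'   rows outside the universe are ignored.
#' @param p_max Raw p-value threshold (default 1e-4).
#' @param fdr_max BH-adjusted threshold (default 0.05).
#' @return Tibble: `term_id`, `term_name`, `n_module`, `n_universe`,
#'   `n_term_universe`, `n_term_module`, `p`, `fdr`. The full tested table
#'   (before thresholding) is attached as `attr(, "tested")`.
#' @export
enrich_terms <- function(module_genes, universe, terms, p_max = 1e-4,
                         fdr_max = 0.05) {
  if (!all(module_genes %in% universe)) {
    abort("module genes must be a subset of the universe")
  }
  terms <- terms[terms$gene_id %in% universe, , drop = FALSE]
  if (!"term_name" %in% names(terms)) terms$term_name <- terms$term_id
  empty <- tibble(term_id = character(0), term_name = character(0),
                  n_module = integer(0), n_universe = integer(0),
                  n_term_universe = integer(0), n_term_module = integer(0),
                  p = double(0), fdr = double(0))
  if (nrow(terms) == 0) return(empty)
  N <- length(unique(universe))
  n_mod <- length(unique(module_genes))
  tested <- terms |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      n_term_universe = dplyr::n_distinct(.data$gene_id),
      n_term_module = dplyr::n_distinct(intersect(.data$gene_id, module_genes)),
      .groups = "drop") |>
    dplyr::filter(.data$n_term_module >= 1) |>
    dplyr::mutate(
      n_module = n_mod, n_universe = N,
      p = phyper(.data$n_term_module - 1L, .data$n_term_universe,
                 N - .data$n_term_universe, n_mod, lower.tail = FALSE),
      fdr = p.adjust(.data$p, method = "BH"))
  if (nrow(tested) == 0) return(empty)
  out <- tested |>
    dplyr::filter(.data$p < p_max, .data$fdr < fdr_max) |>
    dplyr::arrange(.data$p) |>
    dplyr::select("term_id", "term_name", "n_module", "n_universe",
                  "n_term_universe", "n_term_module", "p", "fdr")
  attr(out, "tested") <- tested
  out
}
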