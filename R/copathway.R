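# Co-pathway filter: a candidate cluster passes when its members share
# metabolic-pathway context — (a) at least two genes annotated with the same
# pathway id, and (b) the genes sharing that pathway classified into at least
# two different reactions. By default both criteria are evaluated on the
# same pathway: reactions pooled across unrelated pathways would pass
# clusters whose members share no pathway at all.

#' Evaluate the co-pathway criteria for one cluster
#'
#' @param gene_ids Character vector of cluster member ids.
#' @param annot Pathway annotation tibble (`gene_id`, `pathway_id`,
#'   `reaction_id`); members without annotation are permitted.
#' @param per_pathway If `TRUE` (default) the distinct-reaction requirement
#'   is counted among the genes sharing each pathway; if `FALSE`, criterion
#'   (b) is evaluated cluster-wide across all member annotations.
#' @return A list: `evidence` — tibble with one row per pathway attached to
#'   any member (`pathway_id`, `n_genes`, `n_reactions`) — and `pass`.
#' @export
copathway_pass <- function(gene_ids, annot, per_pathway = TRUE) {
  rows <- annot[annot$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(list(evidence = tibble(pathway_id = character(0),
                                  n_genes = integer(0), n_reactions = integer(0)),
                pass = FALSE))
  }
  evidence <- rows |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(n_genes = dplyr::n_distinct(.data$gene_id),
                     n_reactions = dplyr::n_distinct(.data$reaction_id),
                     .groups = "drop")
  pass <- if (per_pathway) {
    any(evidence$n_genes >= 2 & evidence$n_reactions >= 2)
  } else {
    any(evidence$n_genes >= 2) && dplyr::n_distinct(rows$reaction_id) >= 2
  }
  list(evidence = evidence, pass = pass)
}

#' Apply the co-pathway filter to a candidate set
#'
#' @param clusters Candidate tibble (needs `cluster_id`, `gene_ids`).
#' @param annot Pathway annotation tibble.
#' @inheritParams copathway_pass
#' @return `clusters` with a logical `copathway_pass` column; the per-pathway
#'   evidence for every input cluster is attached as
#'   `attr(, "copathway_report")` (columns `cluster_id`, `pathway_id`,
#'   `n_genes`, `n_reactions`, `pass`).
#' @export
filter_copathway <- function(clusters, annot, per_pathway = TRUE) {
  res <- purrr::map(clusters$gene_ids, copathway_pass, annot = annot,
                    per_pathway = per_pathway)
  clusters$copathway_pass <- vapply(res, `[[`, logical(1), "pass")
  report <- purrr::map2(res, clusters$cluster_id, function(r, cid) {
    ev <- r$evidence
    if (nrow(ev) == 0) {
      ev <- tibble(pathway_id = NA_character_, n_genes = 0L, n_reactions = 0L)
    }
    dplyr::bind_cols(tibble(cluster_id = cid), ev, tibble(pass = r$pass))
  })
  attr(clusters, "copathway_report") <- dplyr::bind_rows(report)
  clusters
}
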