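# Hub-gene scoring: module membership (MM), gene significance (GS) and
# intramodular connectivity, plus the hub-selection rule (MM > 0.8,
# GS > 0.2, top-k by connectivity) and regulator-cluster co-expression.

#' Module membership of genes
#'
#' MM is the absolute Pearson correlation between a gene's expression
#' profile and a module eigengene (absolute values by definition here, as
#' for GS).
#'
#' @param expr Expression matrix.
#' @param modules A `module_set` with eigengenes.
#' @param gene_ids Genes to score (default: all assigned genes, each against
#'   its own module's eigengene).
#' @param module Score all `gene_ids` against this module's eigengene
#'   instead of their own assignments (required for unassigned genes).
#' @return Named numeric vector of MM values in `[0, 1]`.
#' @export
module_membership <- function(expr, modules, gene_ids = NULL, module = NULL) {
  if (is.null(modules$eigengenes)) abort("module_set has no eigengenes")
  values <- expr_values(expr)
  if (!is.null(module)) {
    if (!module %in% colnames(modules$eigengenes)) {
      abort(sprintf("no eigengene for module %s", module))
    }
    gene_ids <- gene_ids %||% modules$assignment$gene_id
    mm <- abs(cor(t(values[gene_ids, , drop = FALSE]),
                  modules$eigengenes[, module]))[, 1]
    return(setNames(mm, gene_ids))
  }
  a <- modules$assignment
  gene_ids <- gene_ids %||% a$gene_id[a$module != "unassigned"]
  mods <- a$module[match(gene_ids, a$gene_id)]
  if (any(is.na(mods)) || any(mods == "unassigned")) {
    abort("gene without a module assignment: pass `module` explicitly")
  }
  out <- vapply(seq_along(gene_ids), function(i) {
    abs(cor(values[gene_ids[i], ], modules$eigengenes[, mods[i]]))
  }, double(1))
  setNames(out, gene_ids)
}

#' Gene significance against a trait
#'
#' GS is the absolute Pearson correlation between a gene's expression and a
#' trait vector (here, typically a BGC member gene's expression profile).
#'
#' @param expr Expression matrix.
#' @param trait Numeric trait vector aligned to samples.
#' @param gene_ids Genes to score (default all).
#' @return Named numeric vector of GS values in `[0, 1]`.
#' @export
gene_significance <- function(expr, trait, gene_ids = NULL) {
  values <- expr_values(expr)
  if (length(trait) != ncol(values)) abort("trait misaligned with samples")
  if (sd(trait) == 0) abort("zero-variance trait")
  gene_ids <- gene_ids %||% rownames(values)
  gs <- abs(cor(t(values[gene_ids, , drop = FALSE]), trait))[, 1]
  setNames(gs, gene_ids)
}

#' Intramodular connectivity
#'
#' `k_within` is the sum of a gene's adjacency weights to the other genes of
#' its own module (diagonal excluded) — the connectivity notion used to rank
#' hub candidates.
#'
#' @param adj Adjacency matrix covering the genes.
#' @param modules A `module_set`.
#' @param gene_ids Genes to score (default: all assigned genes). Requesting
#'   an unassigned gene is an error.
#' @return Named numeric vector of within-module connectivities.
#' @export
intramodular_connectivity <- function(adj, modules, gene_ids = NULL) {
  a <- modules$assignment
  gene_ids <- gene_ids %||% a$gene_id[a$module != "unassigned"]
  mods <- a$module[match(gene_ids, a$gene_id)]
  if (any(is.na(mods)) || any(mods == "unassigned")) {
    bad <- gene_ids[which(is.na(mods) | mods == "unassigned")[1]]
    abort(sprintf("gene %s is not assigned to a module", bad))
  }
  out <- vapply(seq_along(gene_ids), function(i) {
    partners <- setdiff(a$gene_id[a$module == mods[i]], gene_ids[i])
    partners <- intersect(partners, colnames(adj))
    if (length(partners) == 0) return(0)
    sum(adj[gene_ids[i], partners])
  }, double(1))
  setNames(out, gene_ids)
}

#' Score every assigned gene for hub selection
#'
#' Builds the per-gene record used by [select_hubs()]: module label, MM
#' against the gene's own module eigengene, GS against the BGC trait set
#' (by default the maximum GS over all traits — hubs are evaluated against
#' the cluster traits collectively; a single named trait may be requested),
#' and intramodular connectivity.
#'
#' @param expr Expression matrix.
#' @param modules A `module_set` with eigengenes.
#' @param adj Adjacency matrix.
#' @param traits A `trait_set` (or samples x traits matrix).
#' @param trait Optional single trait id to use instead of the max-GS policy.
#' @return Tibble: `gene_id`, `module`, `MM`, `GS`, `k_within`.
#' @export
score_module_genes <- function(expr, modules, adj, traits, trait = NULL) {
  a <- modules$assignment
  gene_ids <- a$gene_id[a$module != "unassigned"]
  if (length(gene_ids) == 0) {
    return(tibble(gene_id = character(0), module = character(0),
                  MM = double(0), GS = double(0), k_within = double(0)))
  }
  tvals <- if (inherits(traits, "trait_set")) traits$values else traits
  if (!is.null(trait)) {
    if (!trait %in% colnames(tvals)) abort(sprintf("unknown trait %s", trait))
    tvals <- tvals[, trait, drop = FALSE]
  }
  values <- expr_values(expr)
  gs <- if (ncol(tvals) == 0) rep(NA_real_, length(gene_ids)) else {
    apply(abs(cor(t(values[gene_ids, , drop = FALSE]), tvals)), 1, max)
  }
  tibble(
    gene_id = gene_ids,
    module = a$module[match(gene_ids, a$gene_id)],
    MM = unname(module_membership(expr, modules, gene_ids)),
    GS = unname(gs),
    k_within = unname(intramodular_connectivity(adj, modules, gene_ids))
  )
}

#' Select hub genes per module
#'
#' Hubs are candidates with `MM > mm_min` and `GS > gs_min`, ranked by
#' intramodular connectivity (descending) within their module and truncated
#' to the `top_k` best; ties break by MM, then lexicographic gene id, so the
#' selection is deterministic under record shuffling.
#'
#' @param records Tibble from [score_module_genes()].
#' @param mm_min Module-membership gate (default 0.8).
#' @param gs_min Gene-significance gate (default 0.2).
#' @param top_k Hubs kept per module (default 30).
#' @return The selected records with `rank` and `is_hub = TRUE`; empty (with
#'   a note) when nothing qualifies.
#' @export
select_hubs <- function(records, mm_min = 0.8, gs_min = 0.2, top_k = 30) {
  qualified <- records |>
    dplyr::filter(.data$MM > mm_min, .data$GS > gs_min) |>
    dplyr::arrange(.data$module, dplyr::desc(.data$k_within),
                   dplyr::desc(.data$MM), .data$gene_id) |>
    dplyr::group_by(.data$module) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::mutate(rank = dplyr::row_number(), is_hub = TRUE) |>
    dplyr::ungroup()
  if (nrow(qualified) == 0) log_msg("no genes pass the hub gates")
  qualified
}

#' Regulator-cluster co-expression matrix
#'
#' Pearson r (with p-values) between each candidate regulator and each
#' member of a candidate cluster. A regulator is summarised as "highly
#' co-expressed" with the cluster when at least `high_fraction` of its
#' entries reach the metabolic-pair null threshold.
#'
#' @param expr Expression matrix.
#' @param regulator_ids Candidate regulator gene ids (non-empty; absent ids
#'   are skipped with a warning).
#' @param cluster_gene_ids Cluster member ids.
#' @param null Optional [build_pcc_null()] result enabling the summary flag.
#' @param high_fraction Fraction of entries that must reach the threshold
#'   (default 0.5).
#' @return A `regulator_matrix`: matrices `r` and `p` (regulators x
#'   members), and `summary` tibble (`regulator`, `n_above`, `fraction`,
#'   `highly_coexpressed`).
#' @export
regulator_cluster_matrix <- function(expr, regulator_ids, cluster_gene_ids,
                                     null = NULL, high_fraction = 0.5) {
  if (length(regulator_ids) == 0) abort("empty regulator set")
  values <- expr_values(expr)
  missing <- setdiff(regulator_ids, rownames(values))
  if (length(missing) > 0) {
    warn(sprintf("skipping %d regulator(s) absent from expression", length(missing)))
    regulator_ids <- setdiff(regulator_ids, missing)
  }
  if (length(regulator_ids) == 0) abort("no regulator has expression data")
  members <- intersect(cluster_gene_ids, rownames(values))
  if (length(members) == 0) abort("no cluster member has expression data")
  r <- cor(t(values[regulator_ids, , drop = FALSE]),
           t(values[members, , drop = FALSE]))
  p <- matrix(pcc_pvalue(r, ncol(values)), nrow(r), ncol(r), dimnames = dimnames(r))
  summary <- tibble(regulator = regulator_ids,
                    n_above = NA_integer_, fraction = NA_real_,
                    highly_coexpressed = NA)
  if (!is.null(null)) {
    rc <- if (isTRUE(null$absolute)) abs(r) else r
    summary$n_above <- as.integer(rowSums(rc >= null$threshold))
    summary$fraction <- summary$n_above / ncol(r)
    summary$highly_coexpressed <- summary$fraction >= high_fraction
  }
  structure(list(r = r, p = p, summary = summary,
                 threshold = null$threshold %||% NA_real_),
            class = "regulator_matrix")
}

#' @export
print.regulator_matrix <- function(x, ...) {
  cat(sprintf("<regulator_matrix> %d regulator(s) x %d cluster gene(s)\n",
              nrow(x$r), ncol(x$r)))
  invisible(x)
}
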