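# Candidate-cluster discovery from a gene table: maximal runs of
# enzyme-annotated genes, a transparent stand-in for dedicated genome-mining
# scanners whose HMM internals are out of scope here.

is_enzyme_gene <- function(genes) {
  vapply(genes$enzyme_classes, function(cl) length(cl) > 0, logical(1))
}

#' Scan a gene table for candidate biosynthetic gene clusters
#'
#' Plant BGCs are runs of two or more non-homologous genes in an adjacent
#' genomic region encoding different enzymes of one pathway, typically 3-10
#' genes. The scanner emits maximal runs of enzyme-annotated genes on one
#' chromosome in which consecutive enzyme genes are at most `max_gap` bp
#' apart with at most `max_intervening` non-enzyme genes between them; runs
#' whose enzyme-gene count falls in `[min_genes, max_genes]` become
#' candidates. Strand is ignored.
#'
#' @param genes Gene table from [read_gene_table()], position-sorted.
#' @param max_gap Maximum bp between the end of one enzyme gene and the start
#'   of the next (default 20 kb).
#' @param min_genes,max_genes Emitted run size range (defaults 3 and 10, the
#'   size range of characterised plant clusters).
#' @param max_intervening Maximum non-enzyme genes tolerated between
#'   consecutive enzyme genes (default 3).
#' @return A tibble of candidates: `cluster_id`, `chrom`, `gene_ids`
#'   (list-column of enzyme members, position-ordered), `span_start`,
#'   `span_end`, `n_genes`, `source = "scanned"`.
#' @export
scan_clusters <- function(genes, max_gap = 20000, min_genes = 3, max_genes = 10,
                          max_intervening = 3) {
  if (max_gap <= 0) abort("max_gap must be positive")
  if (min_genes < 2) abort("min_genes must be >= 2")
  check_position_sorted(genes)
  enz <- is_enzyme_gene(genes)
  runs <- list()
  for (chrom in unique(genes$chrom)) {
    on_chrom <- which(genes$chrom == chrom)
    eidx <- on_chrom[enz[on_chrom]]
    if (length(eidx) == 0) next
    run <- eidx[1]
    for (i in eidx[-1]) {
      prev <- run[length(run)]
      gap <- genes$start[i] - genes$end[prev]
      intervening <- sum(!enz[on_chrom[on_chrom > prev & on_chrom < i]])
      if (gap <= max_gap && intervening <= max_intervening) {
        run <- c(run, i)
      } else {
        runs[[length(runs) + 1L]] <- run
        run <- i
      }
    }
    runs[[length(runs) + 1L]] <- run
  }
  runs <- Filter(function(r) length(r) >= min_genes && length(r) <= max_genes, runs)
  if (length(runs) == 0) {
    return(tibble(cluster_id = character(0), chrom = character(0),
                  gene_ids = list(), span_start = integer(0),
                  span_end = integer(0), n_genes = integer(0),
                  source = character(0)))
  }
  out <- purrr::map(runs, function(r) {
    tibble(chrom = genes$chrom[r[1]],
           gene_ids = list(genes$gene_id[r]),
           span_start = min(genes$start[r]),
           span_end = max(genes$end[r]),
           n_genes = length(r))
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::arrange(out, .data$chrom, .data$span_start)
  out$cluster_id <- sprintf("C%03d", seq_len(nrow(out)))
  out$source <- "scanned"
  out[, c("cluster_id", "chrom", "gene_ids", "span_start", "span_end",
          "n_genes", "source")]
}

check_position_sorted <- function(genes) {
  by_chrom <- split(genes$start, genes$chrom)
  if (any(vapply(by_chrom, is.unsorted, logical(1)))) {
    abort("gene table must be position-sorted within chromosomes (see read_gene_table)")
  }
  invisible(genes)
}

#' Annotate candidate clusters with structural features
#'
#' Fills the structural-feature flags that characterise genuine plant BGCs:
#' `has_p450` (any member's enzyme class matches a cytochrome-P450 synonym,
#' case-insensitively), `enzyme_class_count` (distinct enzyme classes among
#' members) and `nonhomologous` (no single protein family shared by every
#' member — the homology proxy).
#'
#' @param clusters Candidate tibble from [scan_clusters()] or
#'   [read_external_candidates()].
#' @param genes Gene table resolving every member id.
#' @param p450_synonyms Patterns identifying P450 enzyme classes.
#' @return `clusters` with `enzyme_class_count`, `has_p450`, `nonhomologous`
#'   columns added.
#' @export
cluster_features <- function(clusters, genes,
                             p450_synonyms = c("CYP", "P450", "cytochrome P450")) {
  idx <- setNames(seq_len(nrow(genes)), genes$gene_id)
  feats <- purrr::map(clusters$gene_ids, function(members) {
    unknown <- setdiff(members, names(idx))
    if (length(unknown) > 0) {
      abort(sprintf("cluster member %s not present in gene table", unknown[1]))
    }
    classes <- unlist(genes$enzyme_classes[idx[members]])
    fams <- genes$family_ids[idx[members]]
    has_p450 <- any(vapply(classes, function(cl) {
      any(vapply(p450_synonyms, function(s) grepl(s, cl, ignore.case = TRUE),
                 logical(1)))
    }, logical(1)))
    shared_family <- if (any(lengths(fams) == 0)) character(0) else Reduce(intersect, fams)
    tibble(enzyme_class_count = length(unique(classes)),
           has_p450 = has_p450,
           nonhomologous = length(shared_family) == 0)
  })
  dplyr::bind_cols(clusters, dplyr::bind_rows(feats))
}

#' Read an externally predicted candidate-cluster list
#'
#' Ingests cluster predictions from an external genome-mining tool rendered
#' as a two-column TSV (`cluster_id`, `gene_id`). Members are re-sorted by
#' genomic position (with a warning if the file order differed) and
#' structural features are computed as for scanned candidates.
#'
#' @param path TSV path.
#' @param genes Gene table; every listed member must resolve.
#' @inheritParams cluster_features
#' @return Candidate tibble with `source = "external"`.
#' @export
read_external_candidates <- function(path, genes,
                                     p450_synonyms = c("CYP", "P450", "cytochrome P450")) {
  if (!file.exists(path)) abort(sprintf("candidate list not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("cluster_id", "gene_id") %in% names(raw))) {
    abort("external candidate TSV needs columns cluster_id, gene_id")
  }
  idx <- setNames(seq_len(nrow(genes)), genes$gene_id)
  out <- raw |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(gene_ids = list(.data$gene_id), .groups = "drop")
  out$gene_ids <- purrr::map2(out$gene_ids, out$cluster_id, function(members, cid) {
    unknown <- setdiff(members, names(idx))
    if (length(unknown) > 0) {
      abort(sprintf("cluster %s lists gene %s absent from the gene table",
                    cid, unknown[1]))
    }
    sorted <- members[order(genes$start[idx[members]])]
    if (!identical(sorted, members)) {
      warn(sprintf("cluster %s members re-sorted by genomic position", cid))
    }
    sorted
  })
  out$chrom <- vapply(out$gene_ids, function(m) genes$chrom[idx[m[1]]], character(1))
  out$span_start <- vapply(out$gene_ids, function(m) min(genes$start[idx[m]]), integer(1))
  out$span_end <- vapply(out$gene_ids, function(m) max(genes$end[idx[m]]), integer(1))
  out$n_genes <- lengths(out$gene_ids)
  out$source <- "external"
  out <- out[, c("cluster_id", "chrom", "gene_ids", "span_start", "span_end",
                 "n_genes", "source")]
  cluster_features(out, genes, p450_synonyms)
}
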