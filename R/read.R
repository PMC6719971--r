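#' Read a gene annotation table
#'
#' Reads gene models from either a simplified TSV dialect (the canonical
#' interchange format of this package) or a GFF3 file restricted to `gene`
#' features. Coordinates are 1-based inclusive throughout (GFF3 convention);
#' no half-open conversion is ever applied.
#'
#' The TSV dialect has columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' and optionally `enzyme_classes` and `family_ids`, the latter two
#' semicolon-separated lists. Enzyme classes are the per-gene enzyme evidence
#' (e.g. `"CYP450"`, `"UDP-glucosyltransferase"`); family ids are the
#' protein-family labels used as the homology proxy when testing whether a
#' candidate cluster is non-homologous.
#'
#' @param path Path to the annotation file.
#' @param dialect `"tsv"` (default) or `"gff3"`.
#' @param enzyme_attr For GFF3 input, the attribute key holding the
#'   semicolon-separated enzyme-class list (default `"enzyme_class"`).
#' @param family_attr For GFF3 input, the attribute key holding the
#'   protein-family labels (default `"family_id"`).
#'
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#'   and list-columns `enzyme_classes`, `family_ids`, sorted by
#'   `(chrom, start)`. Genes without enzyme annotation carry empty character
#'   vectors (non-enzyme genes).
#' @export
read_gene_table <- function(path, dialect = c("tsv", "gff3"),
                            enzyme_attr = "enzyme_class",
                            family_attr = "family_id") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("gene table not found: %s", path))
  genes <- if (dialect == "tsv") {
    read_gene_tsv(path)
  } else {
    read_gene_gff3(path, enzyme_attr, family_attr)
  }
  validate_gene_table(genes)
}

read_gene_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("gene table %s lacks required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  bad <- which(as.numeric(raw$end) < as.numeric(raw$start))
  if (length(bad) > 0) {
    abort(sprintf("gene table %s: end < start at data line %d (gene %s)",
                  path, bad[1], raw$gene_id[bad[1]]))
  }
  tibble(
    gene_id = raw$gene_id,
    chrom = raw$chrom,
    start = as.integer(as.numeric(raw$start)),
    end = as.integer(as.numeric(raw$end)),
    strand = raw$strand,
    enzyme_classes = split_semicolon(raw[["enzyme_classes"]] %||% rep(NA_character_, nrow(raw))),
    family_ids = split_semicolon(raw[["family_ids"]] %||% rep(NA_character_, nrow(raw)))
  )
}

read_gene_gff3 <- function(path, enzyme_attr, family_attr) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package; use the TSV dialect otherwise")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  meta <- as.data.frame(gr)
  getattr <- function(key) {
    if (key %in% names(meta)) as.character(meta[[key]]) else rep(NA_character_, nrow(meta))
  }
  tibble(
    gene_id = as.character(meta$ID),
    chrom = as.character(meta$seqnames),
    start = as.integer(meta$start),
    end = as.integer(meta$end),
    strand = as.character(meta$strand),
    enzyme_classes = split_semicolon(getattr(enzyme_attr)),
    family_ids = split_semicolon(getattr(family_attr))
  )
}

split_semicolon <- function(x) {
  purrr::map(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}

validate_gene_table <- function(genes) {
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene_id in gene table: %s", dup[1]))
  }
  if (any(genes$start < 1L)) abort("gene coordinates must be 1-based (start >= 1)")
  bad <- which(genes$end < genes$start)
  if (length(bad) > 0) {
    abort(sprintf("end < start for gene %s", genes$gene_id[bad[1]]))
  }
  dplyr::arrange(genes, .data$chrom, .data$start)
}

#' Read a pathway annotation table
#'
#' Reads MetaCyc-style pathway/reaction annotation as emitted by enzyme
#' annotation pipelines: one row per (gene, pathway, reaction) assignment. A
#' gene may carry several rows. These annotations drive the co-pathway filter
#' and define the "metabolic gene" universe of the co-expression null.
#'
#' @param path Path to a TSV with columns `gene_id`, `pathway_id`,
#'   `reaction_id` (all non-empty).
#' @return A tibble with those three character columns.
#' @export
read_pathway_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("pathway annotation not found: %s", path))
  annot <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("gene_id", "pathway_id", "reaction_id")
  missing <- setdiff(required, names(annot))
  if (length(missing) > 0) {
    abort(sprintf("pathway annotation lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  annot <- annot[required]
  if (any(!stats::complete.cases(annot)) || any(vapply(annot, function(c) any(!nzchar(c)), TRUE))) {
    abort("pathway annotation fields must all be non-empty")
  }
  as_tibble(annot)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `timepoint`, `condition`,
#'   `replicate`. The default experimental design this package emulates is
#'   4 time points (3 h, 3 d, 7 d, 14 d) x 2 conditions (mono-culture,
#'   co-culture) x 2 replicates = 16 samples.
#' @return A tibble; `sample_id` is checked unique.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("sample metadata not found: %s", path))
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    timepoint = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer()
  ))
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in sample metadata")
  meta
}

#' Construct an expression matrix object
#'
#' Container for an FPKM-like genes x samples matrix plus sample metadata.
#' Correlation-based statistics need at least 3 samples, so fewer is an error.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Values are expected non-negative
#'   (FPKM-like); negative entries draw a warning, not an error, since every
#'   downstream statistic is correlation-based.
#' @param samples Optional sample metadata tibble (see
#'   [read_sample_metadata()]); joined by `sample_id` = column name.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) abort("`values` must be a numeric matrix")
  if (is.null(rownames(values))) abort("`values` must have gene ids as rownames")
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) abort("duplicate gene ids in expression matrix")
  if (ncol(values) < 3) abort("at least 3 samples required")
  if (!all(apply(values, 1, function(r) any(is.finite(r))))) {
    abort("every gene row must contain at least one finite value")
  }
  if (any(values < 0, na.rm = TRUE)) warn("expression matrix contains negative values")
  if (!is.null(samples)) {
    samples <- as_tibble(samples)
    if (!all(colnames(values) %in% samples$sample_id)) {
      abort("sample metadata does not cover all expression columns")
    }
    samples <- samples[match(colnames(values), samples$sample_id), ]
  } else {
    samples <- tibble(sample_id = colnames(values))
  }
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Accept either an expr_matrix or a bare genes x samples matrix.
expr_values <- function(expr) {
  if (inherits(expr, "expr_matrix")) expr$values
  else if (is.matrix(expr) && is.numeric(expr)) expr
  else abort("expected an `expr_matrix` or a numeric genes x samples matrix")
}

#' Read an expression matrix
#'
#' Reads a TSV whose first column is gene ids and remaining columns are
#' per-sample FPKM-like values. Genes whose rows are entirely missing are
#' dropped (with a logged count); rows with some missing values are mean
#' imputed per gene so that correlation math stays total downstream.
#'
#' @param path Expression TSV.
#' @param samples_path Optional companion sample-metadata TSV.
#' @return An [expr_matrix()] object.
#' @export
read_expression <- function(path, samples_path = NULL) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  gene_ids <- raw[[1]]
  cells <- as.matrix(raw[-1])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                  dimnames = list(gene_ids, colnames(cells))))
  bad <- which(is.na(vals) & !is.na(cells) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric expression value at row %d, column %s",
                  bad[1, 1], colnames(vals)[bad[1, 2]]))
  }
  if (ncol(vals) < 3) abort("at least 3 samples required")
  all_na <- apply(vals, 1, function(r) all(is.na(r)))
  if (any(all_na)) {
    log_msg(sprintf("dropping %d gene(s) with all-missing expression", sum(all_na)))
    warn(sprintf("dropped %d all-missing gene row(s)", sum(all_na)))
    vals <- vals[!all_na, , drop = FALSE]
  }
  n_imputed <- sum(apply(vals, 1, anyNA))
  if (n_imputed > 0) {
    log_msg(sprintf("mean-imputing missing values in %d gene row(s)", n_imputed))
    vals <- t(apply(vals, 1, function(r) {
      r[is.na(r)] <- mean(r, na.rm = TRUE)
      r
    }))
  }
  samples <- if (!is.null(samples_path)) read_sample_metadata(samples_path) else NULL
  expr_matrix(vals, samples)
}
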