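# Co-expression validation: Pearson correlation of member pairs against a
# null built from all metabolic gene pairs, thresholded at a stated
# percentile (default the 95th) of that null distribution.

#' Pearson correlation with a two-sided p-value
#'
#' The p-value uses the exact t transform, `t = r * sqrt((n-2)/(1-r^2))`
#' with `n - 2` degrees of freedom (identical to `cor.test`). Zero-variance
#' input yields `r = NA` with a warning; such pairs are excluded from
#' downstream counts.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with elements `r` and `p`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("correlation needs at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero-variance vector in pcc(); returning r = NA")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- cor(x, y)
  list(r = r, p = pcc_pvalue(r, length(x)))
}

# Vectorised two-sided p-value for Pearson r at sample size n.
pcc_pvalue <- function(r, n) {
  df <- n - 2
  r2 <- pmin(r^2, 1)
  t <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(t, df, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  pmin(p, 1)
}

#' Build the metabolic-pair correlation null
#'
#' Computes Pearson r over all unordered pairs of metabolic genes (genes
#' carrying a pathway annotation) and takes a stated percentile of the
#' signed r distribution as the co-expression threshold, using linear
#' interpolation between order statistics. When the pair count exceeds
#' `max_pairs` a seeded uniform subsample of pairs is scored instead.
#'
#' @param expr [expr_matrix()] or genes x samples matrix.
#' @param metabolic_genes Character vector of metabolic gene ids.
#' @param percentile Percentile of the null taken as threshold (default 95).
#' @param max_pairs Cap on scored pairs (default 2e6).
#' @param seed Seed for pair subsampling; ignored when all pairs fit.
#' @param absolute Use `|r|` instead of signed r (default `FALSE`: the
#'   percentile is taken on the distribution as observed).
#' @return A `pcc_null` object: `threshold`, `percentile`,
#'   `n_pairs_sampled`, `sampling_seed`, and the scored `r` values.
#' @export
build_pcc_null <- function(expr, metabolic_genes, percentile = 95,
                           max_pairs = 2e6, seed = NULL, absolute = FALSE) {
  values <- expr_values(expr)
  present <- intersect(metabolic_genes, rownames(values))
  if (length(present) < 2) abort("need at least 2 metabolic genes with expression")
  V <- values[present, , drop = FALSE]
  sds <- apply(V, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("excluding %d zero-variance metabolic gene(s) from the null",
                 sum(sds == 0)))
    V <- V[sds > 0, , drop = FALSE]
    if (nrow(V) < 2) abort("need at least 2 metabolic genes with expression")
  }
  m <- nrow(V)
  total_pairs <- choose(m, 2)
  sampling_seed <- NA_integer_
  if (total_pairs <= max_pairs && m <= 4000) {
    C <- cor(t(V))
    r <- C[upper.tri(C)]
  } else {
    sampling_seed <- as.integer(seed %||% 0)
    n_take <- as.integer(min(max_pairs, total_pairs))
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(sampling_seed)
    i <- sample.int(m, n_take, replace = TRUE)
    j <- sample.int(m - 1, n_take, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # uniform over ordered pairs, i != j
    Z <- t(scale(t(V)))
    r <- rowSums(Z[i, , drop = FALSE] * Z[j, , drop = FALSE]) / (ncol(V) - 1)
  }
  r <- r[!is.na(r)]
  if (absolute) r <- abs(r)
  threshold <- as.numeric(quantile(r, percentile / 100, type = 7, names = FALSE))
  structure(list(threshold = threshold, percentile = percentile,
                 n_pairs_sampled = length(r), sampling_seed = sampling_seed,
                 absolute = absolute, r_values = r),
            class = "pcc_null")
}

# Save/restore the global RNG state so seeded subsampling does not perturb
# the caller's stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.pcc_null <- function(x, ...) {
  cat(sprintf("<pcc_null> %sth percentile of %d pair r values: threshold %.4f\n",
              fmt_num(x$percentile), x$n_pairs_sampled, x$threshold))
  invisible(x)
}

#' Score within-cluster co-expression against the null
#'
#' All unordered pairs of expressed members are scored; a pair counts as
#' co-expressed when its r reaches the null threshold and its p-value is
#' below 0.05 (the conjunction is configurable). The cluster passes when at
#' least `min_fraction` of scored pairs are co-expressed.
#'
#' @param gene_ids Cluster member ids.
#' @param expr Expression matrix.
#' @param null A [build_pcc_null()] result.
#' @param min_fraction Minimum co-expressed pair fraction (default 0.5).
#' @param require_significant Also require pair p < `p_max` (default TRUE).
#' @param p_max Pair significance level (default 0.05).
#' @return A `cluster_coexpr` list: `pairs` (tibble `gene_i`, `gene_j`, `r`,
#'   `p`), `n_pairs_scored`, `n_pairs_significant`,
#'   `n_pairs_above_threshold`, `fraction`, `pass`, `reason`.
#' @export
cluster_coexpression <- function(gene_ids, expr, null, min_fraction = 0.5,
                                 require_significant = TRUE, p_max = 0.05) {
  values <- expr_values(expr)
  present <- intersect(gene_ids, rownames(values))
  empty_pairs <- tibble(gene_i = character(0), gene_j = character(0),
                        r = double(0), p = double(0))
  if (length(present) < 2) {
    return(structure(list(pairs = empty_pairs, n_pairs_scored = 0L,
                          n_pairs_significant = 0L, n_pairs_above_threshold = 0L,
                          fraction = NA_real_, pass = FALSE,
                          reason = "insufficient expression data"),
                     class = "cluster_coexpr"))
  }
  V <- values[present, , drop = FALSE]
  C <- suppressWarnings(cor(t(V)))
  ut <- which(upper.tri(C), arr.ind = TRUE)
  r <- C[upper.tri(C)]
  if (isTRUE(null$absolute)) r_cmp <- abs(r) else r_cmp <- r
  p <- pcc_pvalue(r, ncol(V))
  pairs <- tibble(gene_i = present[ut[, 1]], gene_j = present[ut[, 2]], r = r, p = p)
  scored <- !is.na(r)
  if (any(!scored)) warn("zero-variance member(s): some pairs excluded from counts")
  n_scored <- sum(scored)
  n_sig <- sum(p[scored] < p_max)
  n_above <- sum(r_cmp[scored] >= null$threshold)
  qualifying <- if (require_significant) {
    sum(r_cmp[scored] >= null$threshold & p[scored] < p_max)
  } else n_above
  fraction <- if (n_scored > 0) qualifying / n_scored else NA_real_
  structure(list(pairs = pairs, n_pairs_scored = n_scored,
                 n_pairs_significant = n_sig, n_pairs_above_threshold = n_above,
                 fraction = fraction,
                 pass = n_scored > 0 && fraction >= min_fraction,
                 reason = NA_character_),
            class = "cluster_coexpr")
}

#' Apply the co-expression filter to a candidate set
#'
#' @param clusters Candidate tibble (`cluster_id`, `gene_ids`).
#' @inheritParams cluster_coexpression
#' @return `clusters` with `coexpr_pass` and `coexpr_fraction` columns; a
#'   per-cluster report is attached as `attr(, "coexpr_report")` and the
#'   per-pair evidence as `attr(, "coexpr_pairs")`.
#' @export
filter_coexpr <- function(clusters, expr, null, min_fraction = 0.5,
                          require_significant = TRUE, p_max = 0.05) {
  res <- purrr::map(clusters$gene_ids, cluster_coexpression, expr = expr,
                    null = null, min_fraction = min_fraction,
                    require_significant = require_significant, p_max = p_max)
  clusters$coexpr_pass <- vapply(res, `[[`, logical(1), "pass")
  clusters$coexpr_fraction <- vapply(res, `[[`, double(1), "fraction")
  attr(clusters, "coexpr_report") <- dplyr::bind_rows(purrr::map2(
    res, clusters$cluster_id, function(r, cid) {
      tibble(cluster_id = cid, n_pairs_scored = r$n_pairs_scored,
             n_pairs_significant = r$n_pairs_significant,
             n_pairs_above_threshold = r$n_pairs_above_threshold,
             fraction = r$fraction, pass = r$pass, reason = r$reason)
    }))
  attr(clusters, "coexpr_pairs") <- dplyr::bind_rows(purrr::map2(
    res, clusters$cluster_id, function(r, cid) {
      dplyr::bind_cols(tibble(cluster_id = rep(cid, nrow(r$pairs))), r$pairs)
    }))
  clusters
}
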