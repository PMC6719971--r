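# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and textbook formulas only.

# Two-pass covariance Pearson correlation.
brute_pcc <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Percentile by explicit linear interpolation between order statistics
# (the type-7 definition written out by hand).
brute_percentile <- function(v, p) {
  v <- sort(v)
  h <- (length(v) - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Triple-loop topological overlap.
brute_tom <- function(A) {
  n <- nrow(A)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- A[i, j]
      for (u in seq_len(n)) {
        if (u != i && u != j) num <- num + A[i, u] * A[u, j]
      }
      ki <- sum(A[i, -i])
      kj <- sum(A[j, -j])
      out[i, j] <- num / (min(ki, kj) + 1 - A[i, j])
    }
  }
  out
}

# Loop-based intramodular connectivity for one gene.
brute_k_within <- function(adj, members, gene) {
  k <- 0
  for (m in setdiff(members, gene)) k <- k + adj[gene, m]
  k
}

# Exact hypergeometric upper tail P(X >= k) by direct summation of the pmf
# written with choose().
brute_hyper_tail <- function(k, K, N, n) {
  total <- 0
  for (x in k:min(K, n)) {
    total <- total + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  total
}

# Exhaustive candidate-run enumeration on a small gene table: all maximal
# chains of enzyme genes whose consecutive links satisfy the gap and
# intervening-gene constraints, filtered to the size range.
brute_scan <- function(genes, max_gap, min_genes, max_genes, max_intervening) {
  enz <- vapply(genes$enzyme_classes, function(cl) length(cl) > 0, logical(1))
  out <- list()
  for (ch in unique(genes$chrom)) {
    rows <- which(genes$chrom == ch)
    eidx <- rows[enz[rows]]
    ne <- length(eidx)
    if (ne == 0) next
    link_ok <- function(a, b) {
      gap <- genes$start[b] - genes$end[a]
      between <- rows[rows > a & rows < b]
      gap <= max_gap && sum(!enz[between]) <= max_intervening
    }
    for (s in seq_len(ne)) {
      for (e in s:ne) {
        idx <- eidx[s:e]
        chain <- TRUE
        if (length(idx) > 1) {
          for (t in seq_len(length(idx) - 1)) {
            if (!link_ok(idx[t], idx[t + 1])) { chain <- FALSE; break }
          }
        }
        if (!chain) next
        maximal_left <- s == 1 || !link_ok(eidx[s - 1], eidx[s])
        maximal_right <- e == ne || !link_ok(eidx[e], eidx[e + 1])
        if (maximal_left && maximal_right &&
            length(idx) >= min_genes && length(idx) <= max_genes) {
          out[[length(out) + 1L]] <- genes$gene_id[idx]
        }
      }
    }
  }
  out
}

# Small helper: build a gene-table tibble from parallel vectors.
toy_genes <- function(gene_id, chrom, start, end, strand = "+",
                      enzyme = "", family = "") {
  n <- length(gene_id)
  tibble::tibble(
    gene_id = gene_id,
    chrom = rep_len(chrom, n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(strand, n),
    enzyme_classes = lapply(rep_len(enzyme, n), function(e) {
      if (!nzchar(e)) character(0) else strsplit(e, ";")[[1]]
    }),
    family_ids = lapply(rep_len(family, n), function(f) {
      if (!nzchar(f)) character(0) else strsplit(f, ";")[[1]]
    })
  )
}

# Expression matrix with named genes from a list of profiles.
toy_expr <- function(profiles, sample_ids = NULL) {
  m <- do.call(rbind, profiles)
  rownames(m) <- names(profiles)
  colnames(m) <- sample_ids %||% paste0("S", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# module_set built directly from a label vector (bypasses detection).
new_mods <- function(labels, gene_ids) {
  ms <- clustermod:::new_module_set(tibble::tibble(gene_id = gene_ids,
                                                   module = labels))
  ms$assignment <- clustermod:::relabel_by_size(ms$assignment)
  ms
}
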