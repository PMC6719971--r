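# Weighted co-expression network construction: soft-threshold adjacency,
# topological overlap, average-linkage tree cut into modules, eigengenes,
# eigengene-based module merging, and module-trait correlation.

#' Network-stage configuration
#'
#' @param power Soft-threshold exponent, or `"auto"` to choose it by the
#'   scale-free topology criterion ([pick_soft_threshold()]).
#' @param network_type `"unsigned"` (`|r|^beta`, default) or `"signed"`
#'   (`((1+r)/2)^beta`).
#' @param merge_cut_height Eigengene dissimilarity below which modules are
#'   merged (default 0.25, i.e. eigengene correlation above 0.75).
#' @param min_module_size Clusters smaller than this become "unassigned"
#'   (default 30).
#' @param cut_height Static tree-cut height on the `1 - TOM` scale, or
#'   `"auto"`: `0.99 x` the tallest merge, capped at `cut_height_cap`.
#' @param cut_height_cap Cap for the automatic cut (default 0.85); see the
#'   methods vignette for why the cut must stay below the height at which
#'   unrelated background genes start attaching to modules.
#' @param cut_rescue Ladder of higher cut heights at which genes still
#'   unassigned after the capped cut are re-clustered; rescued clusters must
#'   clear the size floor and an internal-coherence gate (mean absolute
#'   correlation with their own eigengene of at least `kme_min`). Set to
#'   `numeric(0)` to disable.
#' @param kme_min After merging, members whose absolute correlation with
#'   their module eigengene falls below this are returned to "unassigned"
#'   (default 0.6; 0 disables the cleanup).
#' @param max_block_size Genes are processed in correlation-guided blocks of
#'   at most this size (default 8000).
#' @param scale_free_fit_target Target signed R^2 for the scale-free fit
#'   (default 0.8).
#' @param candidate_powers Powers swept when `power = "auto"`.
#' @return A `network_config` list.
#' @export
network_config <- function(power = "auto",
                           network_type = c("unsigned", "signed"),
                           merge_cut_height = 0.25, min_module_size = 30,
                           cut_height = "auto", cut_height_cap = 0.85,
                           cut_rescue = c(0.90, 0.95),
                           kme_min = 0.6, max_block_size = 8000,
                           scale_free_fit_target = 0.8,
                           candidate_powers = c(1:10, seq(12, 20, 2))) {
  if (merge_cut_height <= 0 || merge_cut_height >= 1) {
    abort("merge_cut_height must be in (0, 1)")
  }
  network_type <- match.arg(network_type)
  structure(list(power = power, network_type = network_type,
                 merge_cut_height = merge_cut_height,
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, cut_height_cap = cut_height_cap,
                 cut_rescue = cut_rescue, kme_min = kme_min, max_block_size = as.integer(max_block_size),
                 scale_free_fit_target = scale_free_fit_target,
                 candidate_powers = as.integer(candidate_powers)),
            class = "network_config")
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the whole-network connectivity `k_i = sum_j
#' a_ij` is computed, `log10 k` is binned, and `log10 p(k)` is regressed on
#' `log10 k`; the fit is the signed R^2 of that regression (negated when
#' the slope is positive, since scale-free topology requires a decreasing
#' frequency law). The smallest power reaching `target_fit` is returned;
#' when no candidate reaches it, the standard sample-count-based default
#' power is used instead (6 for fewer than 20 samples in an unsigned
#' network), with a warning.
#'
#' @param expr Expression matrix ([expr_matrix()] or genes x samples matrix).
#' @param candidate_powers Integer powers to sweep.
#' @param target_fit Signed R^2 to reach (default 0.8).
#' @param network_type `"unsigned"` or `"signed"`.
#' @param n_bins Connectivity histogram bins (default 10).
#' @return A `soft_threshold_fit`: `power` (the choice) and `table`, a
#'   tibble with `power`, `fit`, `slope`, `mean_k`, `median_k`, `max_k`.
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, seq(12, 20, 2)),
                                target_fit = 0.8,
                                network_type = c("unsigned", "signed"),
                                n_bins = 10) {
  network_type <- match.arg(network_type)
  values <- expr_values(expr)
  if (nrow(values) < 50) warn("fewer than 50 genes: scale-free fit is unreliable")
  sds <- apply(values, 1, sd)
  if (all(sds == 0)) abort("constant expression matrix")
  values <- values[sds > 0, , drop = FALSE]
  C <- cor(t(values))
  rows <- purrr::map(candidate_powers, function(beta) {
    A <- raise_adjacency(C, beta, network_type)
    k <- rowSums(A) - 1
    sf <- scale_free_fit(k, n_bins)
    tibble(power = beta, fit = sf$fit, slope = sf$slope,
           mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  table <- dplyr::bind_rows(rows)
  if (length(candidate_powers) == 1) {
    return(structure(list(power = candidate_powers, table = table,
                          target_fit = target_fit),
                     class = "soft_threshold_fit"))
  }
  fits <- ifelse(is.na(table$fit), -Inf, table$fit)
  ok <- which(fits >= target_fit)
  power <- if (length(ok) > 0) {
    table$power[ok[1]]
  } else {
    # When no power reaches the fit target (common when the data are not
    # scale-free), fall back to the standard sample-count-based default
    # rather than over-thresholding at the power of maximal fit.
    fallback <- default_power(ncol(values), network_type)
    best <- if (any(is.finite(fits))) max(fits[is.finite(fits)]) else NA_real_
    warn(sprintf(
      "no power reached scale-free fit %.2f (best %s); using the standard default %d for %d samples",
      target_fit, fmt_num(best), fallback, ncol(values)))
    fallback
  }
  structure(list(power = power, table = table, target_fit = target_fit),
            class = "soft_threshold_fit")
}

# Field-standard default powers by sample count, used when the scale-free
# fit target cannot be reached (signed networks use the doubled value).
default_power <- function(n_samples, network_type) {
  unsigned <- if (n_samples < 20) 6L else if (n_samples < 30) 8L
              else if (n_samples < 40) 10L else 12L
  if (network_type == "signed") 2L * unsigned else unsigned
}

raise_adjacency <- function(C, beta, network_type) {
  A <- if (network_type == "signed") ((1 + C) / 2)^beta else abs(C)^beta
  diag(A) <- 1
  A
}

# Signed R^2 of log10 p(k) ~ log10 k over equal-width log-k bins.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2 || diff(range(log10(k))) < .Machine$double.eps^0.5) {
    return(list(fit = NA_real_, slope = NA_real_))
  }
  bins <- cut(log10(k), breaks = n_bins)
  counts <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  keep <- !is.na(counts) & counts > 0
  if (sum(keep) < 3) return(list(fit = NA_real_, slope = NA_real_))
  x <- log10(mean_k[keep])
  y <- log10(counts[keep] / sum(counts[keep]))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(fit = if (slope < 0) r2 else -r2, slope = slope)
}

#' @export
print.soft_threshold_fit <- function(x, ...) {
  cat(sprintf("<soft_threshold_fit> chosen power %d (target fit %.2f)\n",
              x$power, x$target_fit))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' Soft-threshold adjacency matrix
#'
#' `a_ij = |cor(x_i, x_j)|^beta` (unsigned) or `((1 + cor)/2)^beta`
#' (signed); unit diagonal. Zero-variance genes are excluded with a warning.
#'
#' @inheritParams pick_soft_threshold
#' @param power Soft-threshold exponent (>= 1).
#' @return Symmetric gene x gene matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(expr, power = 6,
                             network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  if (power < 1) abort("power must be >= 1")
  values <- expr_values(expr)
  sds <- apply(values, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("excluding %d zero-variance gene(s) from the network", sum(sds == 0)))
    values <- values[sds > 0, , drop = FALSE]
  }
  raise_adjacency(cor(t(values)), power, network_type)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`. Shared network
#' neighbourhoods smooth the raw adjacency, which stabilises module
#' detection.
#'
#' @param adj Symmetric adjacency with unit diagonal, entries in `[0, 1]`.
#' @return Symmetric TOM matrix, entries in `[0, 1]`, unit diagonal.
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) abort("adjacency must be symmetric")
  if (any(adj < -1e-12) || any(adj > 1 + 1e-12)) abort("adjacency entries must lie in [0, 1]")
  if (any(abs(diag(adj) - 1) > 1e-12)) abort("adjacency must have unit diagonal")
  L <- adj %*% adj - 2 * adj          # sum over u != i,j of a_iu a_uj
  k <- rowSums(adj) - 1
  tom <- (L + adj) / (outer(k, k, pmin) + 1 - adj)
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect modules by static tree cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a static
#' height; clusters smaller than `min_module_size` are pooled into the
#' reserved `"unassigned"` label, and surviving modules are labelled
#' `M1, M2, ...` by decreasing size.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @inheritParams network_config
#' @return A `module_set` with the assignment (no eigengenes yet; see
#'   [compute_eigengenes()] / [merge_close_modules()]).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = "auto",
                           cut_height_cap = 0.85) {
  ids <- rownames(tom) %||% sprintf("g%d", seq_len(nrow(tom)))
  if (nrow(tom) < min_module_size) {
    warn("fewer genes than min_module_size: everything unassigned")
    return(new_module_set(tibble(gene_id = ids,
                                 module = rep("unassigned", length(ids)))))
  }
  tree <- hclust(as.dist(1 - tom), method = "average")
  h <- if (identical(cut_height, "auto")) {
    min(0.99 * max(tree$height), cut_height_cap)
  } else cut_height
  cl <- cutree(tree, h = h)
  assignment <- tibble(gene_id = ids, module = as.character(cl))
  assignment <- drop_small_and_relabel(assignment, min_module_size)
  new_module_set(assignment, tree = tree, cut_height = h)
}

# Multi-pass rescue: re-cluster only the still-unassigned genes at a ladder
# of higher cut heights, accepting clusters that are large enough AND
# internally coherent (mean |cor(member, cluster eigengene)| >= kme_min).
# Modules found earlier are excluded from later passes, so genuine modules
# can never fuse through a high cut; incoherent background blobs are
# rejected by the coherence gate.
rescue_modules <- function(tom, values, assignment, min_module_size,
                           heights, kme_min) {
  if (length(heights) == 0) return(assignment)
  for (h in sort(heights)) {
    una <- which(assignment$module == "unassigned")
    if (length(una) < min_module_size) break
    sub <- tom[una, una, drop = FALSE]
    tree <- hclust(as.dist(1 - sub), method = "average")
    cl <- cutree(tree, h = min(h, 0.99 * max(tree$height)))
    for (lab in unique(cl)) {
      members <- una[cl == lab]
      if (length(members) < min_module_size) next
      ids <- assignment$gene_id[members]
      eg <- tryCatch(module_eigengene(values, ids), error = function(e) NULL)
      if (is.null(eg)) next
      kme <- abs(cor(t(values[ids, , drop = FALSE]), eg$eigengene))
      if (mean(kme, na.rm = TRUE) >= max(kme_min, 0.5)) {
        assignment$module[members] <- paste0("r", h * 100, "_", lab)
      }
    }
  }
  assignment
}

drop_small_and_relabel <- function(assignment, min_module_size) {
  sizes <- table(assignment$module[assignment$module != "unassigned"])
  small <- names(sizes)[sizes < min_module_size]
  assignment$module[assignment$module %in% small] <- "unassigned"
  relabel_by_size(assignment)
}

# Deterministic labels: M1, M2, ... by decreasing size, ties by first
# appearance in the gene table order.
relabel_by_size <- function(assignment) {
  mods <- assignment$module[assignment$module != "unassigned"]
  if (length(mods) == 0) return(assignment)
  first_seen <- tapply(seq_along(assignment$module), assignment$module, min)
  sizes <- table(assignment$module)
  labels <- setdiff(names(sizes), "unassigned")
  ord <- labels[order(-sizes[labels], first_seen[labels])]
  map <- setNames(sprintf("M%d", seq_along(ord)), ord)
  assignment$module <- ifelse(assignment$module == "unassigned", "unassigned",
                              map[assignment$module])
  assignment
}

new_module_set <- function(assignment, eigengenes = NULL, var_explained = NULL,
                           tree = NULL, cut_height = NULL, power = NULL,
                           fit = NULL) {
  structure(list(assignment = assignment, eigengenes = eigengenes,
                 var_explained = var_explained, tree = tree,
                 cut_height = cut_height, power = power, fit = fit),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- length(module_labels(x))
  n_un <- sum(x$assignment$module == "unassigned")
  cat(sprintf("<module_set> %d module(s), %d gene(s), %d unassigned\n",
              n_mod, nrow(x$assignment), n_un))
  invisible(x)
}

module_labels <- function(modules) {
  setdiff(unique(modules$assignment$module), "unassigned")
}

module_members <- function(modules, label) {
  modules$assignment$gene_id[modules$assignment$module == label]
}

#' Module eigengene: first principal component over samples
#'
#' Member rows are standardised (zero mean, unit variance per gene) and the
#' eigengene is the first right-singular vector over samples (unit norm),
#' sign-aligned so its correlation with the module's mean standardised
#' profile is non-negative (first nonzero coordinate positive when that
#' correlation is undefined). `var_explained` is the first singular value's
#' share of total variance.
#'
#' @param expr Expression matrix.
#' @param members Gene ids of the module.
#' @return A list: `eigengene` (named by sample) and `var_explained`.
#' @export
module_eigengene <- function(expr, members) {
  values <- expr_values(expr)
  missing <- setdiff(members, rownames(values))
  if (length(missing) > 0) abort(sprintf("unknown gene in module: %s", missing[1]))
  V <- values[members, , drop = FALSE]
  sds <- apply(V, 1, sd)
  if (all(sds == 0)) abort("all member rows are constant; eigengene undefined")
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant member row(s) from eigengene", sum(sds == 0)))
    V <- V[sds > 0, , drop = FALSE]
  }
  X <- t(scale(t(V)))
  sv <- svd(X)
  eigengene <- sv$v[, 1]
  cm <- colMeans(X)
  algn <- if (sd(cm) > 0 && sd(eigengene) > 0) cor(eigengene, cm) else 0
  if (is.na(algn)) algn <- 0
  if (algn < 0 || (algn == 0 && eigengene[which(abs(eigengene) > 0)[1]] < 0)) {
    eigengene <- -eigengene
  }
  names(eigengene) <- colnames(values)
  list(eigengene = eigengene, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Fill eigengenes and explained variance for every module
#'
#' @param modules A `module_set`.
#' @param expr Expression matrix.
#' @return The `module_set` with `eigengenes` (samples x modules matrix) and
#'   `var_explained` filled.
#' @export
compute_eigengenes <- function(modules, expr) {
  labels <- module_labels(modules)
  if (length(labels) == 0) {
    modules$eigengenes <- NULL
    modules$var_explained <- NULL
    return(modules)
  }
  res <- purrr::map(labels, function(m) {
    module_eigengene(expr, module_members(modules, m))
  })
  modules$eigengenes <- vapply(res, `[[`, double(ncol(expr_values(expr))), "eigengene")
  colnames(modules$eigengenes) <- labels
  rownames(modules$eigengenes) <- colnames(expr_values(expr))
  modules$var_explained <- setNames(vapply(res, `[[`, double(1), "var_explained"),
                                    labels)
  modules
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the smallest eigengene
#' dissimilarity `1 - cor(ME_i, ME_j)` while it is below
#' `merge_cut_height`, recomputing eigengenes after every merge. Labels are
#' refreshed (`M1...` by size) at the end.
#'
#' @param modules A `module_set`.
#' @param expr Expression matrix.
#' @param merge_cut_height Dissimilarity threshold (default 0.25).
#' @return The merged `module_set`, eigengenes recomputed.
#' @export
merge_close_modules <- function(modules, expr, merge_cut_height = 0.25) {
  repeat {
    modules <- compute_eigengenes(modules, expr)
    labels <- module_labels(modules)
    if (length(labels) < 2) break
    D <- 1 - cor(modules$eigengenes)
    diag(D) <- Inf
    if (min(D) >= merge_cut_height) break
    ij <- which(D == min(D), arr.ind = TRUE)[1, ]
    from <- labels[max(ij)]
    to <- labels[min(ij)]
    modules$assignment$module[modules$assignment$module == from] <- to
  }
  modules$assignment <- relabel_by_size(modules$assignment)
  compute_eigengenes(modules, expr)
}

#' Build the full module set from expression
#'
#' End-to-end network stage: soft-threshold selection (unless `power` is
#' fixed), adjacency, TOM, static tree cut, eigengene merge and a
#' module-membership cleanup that returns weakly connected members (|cor
#' with ME| < `kme_min`) to "unassigned". Matrices larger than
#' `max_block_size` genes are processed in correlation-guided blocks
#' (deterministic k-means seeding) and the per-block modules merged by
#' eigengene similarity. The whole stage is deterministic given the input
#' matrix and configuration.
#'
#' @param expr Expression matrix.
#' @param config A [network_config()].
#' @param keep_adjacency Keep the adjacency matrix in the result (single
#'   block only; used by connectivity scoring downstream).
#' @return A `module_set` with eigengenes, `power` and the soft-threshold
#'   fit table filled; adjacency in `$adjacency` when requested.
#' @export
build_modules <- function(expr, config = network_config(), keep_adjacency = FALSE) {
  values <- expr_values(expr)
  sds <- apply(values, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("excluding %d zero-variance gene(s) from the network", sum(sds == 0)))
    values <- values[sds > 0, , drop = FALSE]
  }
  n <- nrow(values)
  fit <- NULL
  if (identical(config$power, "auto")) {
    sub <- values
    if (n > config$max_block_size) {
      sub <- values[round(seq(1, n, length.out = config$max_block_size)), , drop = FALSE]
    }
    fit <- suppressWarnings(
      pick_soft_threshold(sub, config$candidate_powers,
                          config$scale_free_fit_target, config$network_type))
    power <- fit$power
  } else {
    power <- config$power
  }

  blocks <- if (n > config$max_block_size) {
    split_blocks(values, config$max_block_size)
  } else list(seq_len(n))

  assignment <- NULL
  adjacency <- NULL
  offset <- 0L
  parts <- purrr::map(blocks, function(idx) {
    adj <- raise_adjacency(cor(t(values[idx, , drop = FALSE])), power,
                           config$network_type)
    if (length(blocks) == 1 && keep_adjacency) adjacency <<- adj
    tom <- topological_overlap(adj)
    ms <- detect_modules(tom, config$min_module_size, config$cut_height,
                         config$cut_height_cap)
    a <- rescue_modules(tom, values[idx, , drop = FALSE], ms$assignment,
                        config$min_module_size, config$cut_rescue,
                        config$kme_min)
    a$module <- ifelse(a$module == "unassigned", "unassigned",
                       paste0("b", offset, "_", a$module))
    offset <<- offset + 1L
    a
  })
  assignment <- dplyr::bind_rows(parts)
  modules <- new_module_set(assignment, power = power, fit = fit)
  modules <- merge_close_modules(modules, values, config$merge_cut_height)
  modules <- kme_cleanup(modules, values, config$kme_min, config$min_module_size)
  modules$power <- power
  modules$fit <- fit
  if (keep_adjacency && !is.null(adjacency)) modules$adjacency <- adjacency
  modules
}

# Return members weakly correlated with their module eigengene to
# "unassigned", then re-apply the size floor and refresh labels/eigengenes.
kme_cleanup <- function(modules, values, kme_min, min_module_size) {
  if (kme_min <= 0 || is.null(modules$eigengenes)) return(modules)
  a <- modules$assignment
  for (m in module_labels(modules)) {
    idx <- which(a$module == m)
    mm <- abs(cor(t(values[a$gene_id[idx], , drop = FALSE]),
                  modules$eigengenes[, m]))
    a$module[idx[is.na(mm) | mm < kme_min]] <- "unassigned"
  }
  a <- drop_small_and_relabel(a, min_module_size)
  modules$assignment <- a
  compute_eigengenes(modules, values)
}

# Deterministic correlation-profile blocks: k-means over standardised rows
# with centres initialised at evenly spaced genes.
split_blocks <- function(values, max_block_size) {
  n <- nrow(values)
  n_blocks <- ceiling(n / max_block_size)
  X <- t(scale(t(values)))
  centres <- X[round(seq(1, n, length.out = n_blocks)), , drop = FALSE]
  km <- suppressWarnings(kmeans(X, centers = centres, iter.max = 25))
  groups <- split(seq_len(n), km$cluster)
  # k-means balances only approximately; split any oversized group further
  out <- list()
  for (g in groups) {
    while (length(g) > max_block_size) {
      out[[length(out) + 1L]] <- g[seq_len(max_block_size)]
      g <- g[-seq_len(max_block_size)]
    }
    out[[length(out) + 1L]] <- g
  }
  out
}

#' Assemble BGC traits from validated clusters
#'
#' Each member gene of each validated cluster contributes one trait: its
#' expression profile across samples, named `"<cluster_id>:<gene_id>"`.
#' Correlating module eigengenes with these traits asks which regulatory
#' modules track the cluster's expression.
#'
#' @param clusters Validated candidate tibble (`cluster_id`, `gene_ids`).
#' @param expr Expression matrix.
#' @return A `trait_set`: `values` (samples x traits matrix) and
#'   `provenance` (tibble `trait_id`, `cluster_id`, `gene_id`).
#' @export
build_bgc_traits <- function(clusters, expr) {
  values <- expr_values(expr)
  prov <- list()
  cols <- list()
  for (i in seq_len(nrow(clusters))) {
    for (g in clusters$gene_ids[[i]]) {
      if (!g %in% rownames(values)) {
        warn(sprintf("trait member %s absent from expression; skipped", g))
        next
      }
      tid <- paste0(clusters$cluster_id[i], ":", g)
      cols[[tid]] <- values[g, ]
      prov[[length(prov) + 1L]] <- tibble(trait_id = tid,
                                          cluster_id = clusters$cluster_id[i],
                                          gene_id = g)
    }
  }
  if (length(cols) == 0) {
    warn("no expressed cluster members; empty trait set")
    return(structure(list(values = matrix(0, ncol(values), 0,
                                          dimnames = list(colnames(values), NULL)),
                          provenance = tibble(trait_id = character(0),
                                              cluster_id = character(0),
                                              gene_id = character(0))),
                     class = "trait_set"))
  }
  structure(list(values = do.call(cbind, cols), provenance = dplyr::bind_rows(prov)),
            class = "trait_set")
}

#' @export
print.trait_set <- function(x, ...) {
  cat(sprintf("<trait_set> %d trait(s) over %d samples\n",
              ncol(x$values), nrow(x$values)))
  invisible(x)
}

#' Correlate module eigengenes with traits
#'
#' Pearson r and its t-transform p-value for every (module, trait) pair; a
#' cell is significant under the conjunction `p < 0.05` and `r^2 > 0.5`
#' (interpreting the squared-correlation rule as |r| > 0.707). The sign of
#' r distinguishes positive from negative co-regulation.
#'
#' @param modules A `module_set` with eigengenes.
#' @param traits A [build_bgc_traits()] result (or samples x traits matrix
#'   with matching sample names).
#' @param p_max,r2_min Significance rule (defaults 0.05 and 0.5).
#' @return A `module_trait_cor`: matrices `r`, `p`, `significant`, sample
#'   count `n`.
#' @export
module_trait_correlation <- function(modules, traits, p_max = 0.05, r2_min = 0.5) {
  if (is.null(modules$eigengenes)) abort("module_set has no eigengenes; run compute_eigengenes()")
  tvals <- if (inherits(traits, "trait_set")) traits$values else traits
  if (!identical(rownames(modules$eigengenes), rownames(tvals))) {
    abort("samples misaligned between eigengenes and traits")
  }
  r <- cor(modules$eigengenes, tvals)
  n <- nrow(tvals)
  p <- matrix(pcc_pvalue(r, n), nrow(r), ncol(r), dimnames = dimnames(r))
  structure(list(r = r, p = p, significant = (p < p_max) & (r^2 > r2_min), n = n,
                 p_max = p_max, r2_min = r2_min),
            class = "module_trait_cor")
}

#' @export
print.module_trait_cor <- function(x, ...) {
  cat(sprintf("<module_trait_cor> %d module(s) x %d trait(s); %d significant cell(s)\n",
              nrow(x$r), ncol(x$r), sum(x$significant)))
  invisible(x)
}
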