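# Synthetic-data generator: genomes, pathway annotations and expression
# matrices with planted clusters, modules, hubs and regulators, plus a
# ground-truth ledger sufficient to score every downstream stage.

#' Specify a planted biosynthetic gene cluster
#'
#' A planted cluster is laid as `size` adjacent genes on one chromosome. When
#' `co_expressed`, its members load on a shared latent factor; members are
#' annotated with one pathway and `n_reactions` distinct reactions so the
#' co-pathway rules can be exercised in both directions.
#'
#' @param size Number of member genes, in `[3, 10]` (the size range of
#'   functionally characterised plant BGCs).
#' @param co_expressed Do members share a latent expression factor?
#' @param has_p450 Include a cytochrome P450 member (a hallmark of known
#'   plant clusters)?
#' @param n_enzyme_classes Number of distinct enzyme classes among members
#'   (>= 2 for a realistic cluster).
#' @param pathway_id MetaCyc-style pathway identifier; `NULL` auto-names.
#' @param n_reactions Distinct MetaCyc-style reaction ids distributed over
#'   members. `1` produces a cluster that fails the co-pathway reaction rule.
#' @param loading_range Range of member loadings on the cluster factor.
#' @param homologous If `TRUE` all members share one protein family id,
#'   violating the non-homology requirement.
#' @return A `planted_cluster` spec (list).
#' @export
planted_cluster <- function(size = 5, co_expressed = TRUE, has_p450 = TRUE,
                            n_enzyme_classes = 3, pathway_id = NULL,
                            n_reactions = 3, loading_range = c(0.85, 0.95),
                            homologous = FALSE) {
  if (size < 3 || size > 10) abort("planted cluster size must be in [3, 10]")
  if (n_enzyme_classes < 1) abort("n_enzyme_classes must be >= 1")
  structure(list(size = as.integer(size), co_expressed = isTRUE(co_expressed),
                 has_p450 = isTRUE(has_p450),
                 n_enzyme_classes = as.integer(n_enzyme_classes),
                 pathway_id = pathway_id, n_reactions = as.integer(n_reactions),
                 loading_range = loading_range, homologous = isTRUE(homologous),
                 kind = "true"),
            class = "planted_cluster")
}

#' Specify a single-defect decoy cluster
#'
#' Each decoy violates exactly one validation criterion, so the filter stages
#' can be scored individually: `no_copathway` members share a pathway but a
#' single reaction; `no_coexpression` members are independent noise;
#' `homologous` members all share one protein family.
#'
#' @param kind One of `"no_copathway"`, `"no_coexpression"`, `"homologous"`.
#' @param size Member count (default 5).
#' @return A `planted_cluster` spec with `kind` recorded.
#' @export
negative_cluster <- function(kind = c("no_copathway", "no_coexpression", "homologous"),
                             size = 5) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    no_copathway = planted_cluster(size, co_expressed = TRUE, n_reactions = 1),
    no_coexpression = planted_cluster(size, co_expressed = FALSE, n_reactions = 3),
    homologous = planted_cluster(size, co_expressed = TRUE, n_reactions = 3,
                                 n_enzyme_classes = 1, homologous = TRUE)
  )
  spec$kind <- kind
  spec
}

#' Specify a planted co-expression module
#'
#' Module members load on a shared latent factor (the generative analogue of
#' a module eigengene). Designated hub genes load near `hub_loading`; the
#' module factor can be tied to a planted cluster's factor at a stated
#' correlation, planting a module-trait link.
#'
#' @param size Member count.
#' @param loading_range Loadings of ordinary members, drawn uniformly.
#' @param n_hubs Number of designated hub genes.
#' @param hub_loading Loading of hub genes on the module factor.
#' @param trait_link Optional `list(cluster = <index into planted_clusters>,
#'   r = <correlation>)` linking the module factor to that cluster's factor.
#' @return A `planted_module` spec (list).
#' @export
planted_module <- function(size = 100, loading_range = c(0.6, 0.9),
                           n_hubs = 0, hub_loading = 0.95, trait_link = NULL) {
  if (size < 1) abort("module size must be positive")
  if (n_hubs > size) abort("n_hubs cannot exceed module size")
  structure(list(size = as.integer(size), loading_range = loading_range,
                 n_hubs = as.integer(n_hubs), hub_loading = hub_loading,
                 trait_link = trait_link),
            class = "planted_module")
}

#' Specify planted upstream regulators for a cluster
#'
#' Regulator genes are placed away from the cluster (background positions,
#' no enzyme annotation — think transcription factors) but share the
#' cluster's latent factor at the given loading, so regulator-cluster
#' co-expression matrices have a recoverable positive control.
#'
#' @param cluster Index into the scenario's `planted_clusters`.
#' @param n Number of regulator genes.
#' @param loading Loading on the cluster factor.
#' @return A `planted_regulator` spec (list).
#' @export
planted_regulator <- function(cluster = 1, n = 2, loading = 0.9) {
  structure(list(cluster = as.integer(cluster), n = as.integer(n),
                 loading = loading),
            class = "planted_regulator")
}

#' Assemble a synthetic-scenario configuration
#'
#' @param n_genes Total genes across all chromosomes.
#' @param n_chroms Number of chromosomes.
#' @param n_samples Number of samples; the default 16 mirrors the emulated
#'   study design (4 time points x mono-/co-culture x 2 replicates).
#' @param planted_clusters List of [planted_cluster()] / [negative_cluster()]
#'   specs.
#' @param planted_modules List of [planted_module()] specs.
#' @param planted_regulators List of [planted_regulator()] specs.
#' @param noise_sd Standard deviation of per-gene Gaussian noise around the
#'   latent-factor signal (must be > 0).
#' @param n_background_metabolic Background genes given an enzyme class and a
#'   private pathway/reaction annotation; they populate the metabolic-pair
#'   null without forming clusters (background intergenic gaps exceed the
#'   default scan gap).
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_genes = 600, n_chroms = 2, n_samples = 16,
                            planted_clusters = list(),
                            planted_modules = list(),
                            planted_regulators = list(),
                            noise_sd = 0.3,
                            n_background_metabolic = 100,
                            seed = 1) {
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  cluster_genes <- sum(vapply(planted_clusters, `[[`, integer(1), "size"))
  module_genes <- sum(vapply(planted_modules, function(m) m$size, integer(1)))
  regulator_genes <- sum(vapply(planted_regulators, function(r) r$n, integer(1)))
  if (n_genes < cluster_genes + module_genes + regulator_genes + n_background_metabolic) {
    abort("n_genes too small for the planted structures (infeasible placement)")
  }
  structure(list(n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
                 n_samples = as.integer(n_samples),
                 planted_clusters = planted_clusters,
                 planted_modules = planted_modules,
                 planted_regulators = planted_regulators,
                 noise_sd = noise_sd,
                 n_background_metabolic = as.integer(n_background_metabolic),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' The default synthetic scenario
#'
#' Four true planted clusters plus one decoy of each defect kind, three
#' planted modules (one linked to cluster 1 at r = 0.9) with designated hubs,
#' and two planted regulators for cluster 1 — the standard end-to-end
#' exercise for the validation funnel, module recovery, trait detection, hub
#' selection and regulator scoring.
#'
#' @param seed Integer seed.
#' @param n_samples Sample count (default 16).
#' @return A `scenario_config`.
#' @export
default_scenario <- function(seed = 1, n_samples = 16) {
  scenario_config(
    n_genes = 700, n_chroms = 2, n_samples = n_samples,
    planted_clusters = list(
      planted_cluster(size = 5, pathway_id = "PWY-0001"),
      planted_cluster(size = 6, pathway_id = "PWY-0002"),
      planted_cluster(size = 7, pathway_id = "PWY-0003"),
      planted_cluster(size = 4, pathway_id = "PWY-0004"),
      negative_cluster("no_copathway"),
      negative_cluster("no_coexpression"),
      negative_cluster("homologous")
    ),
    planted_modules = list(
      planted_module(120, loading_range = c(0.6, 0.85), n_hubs = 3,
                     trait_link = list(cluster = 1, r = 0.9)),
      planted_module(80, loading_range = c(0.6, 0.85), n_hubs = 3),
      planted_module(60, loading_range = c(0.6, 0.85), n_hubs = 3)
    ),
    planted_regulators = list(planted_regulator(cluster = 1, n = 2, loading = 0.9)),
    noise_sd = 0.3,
    n_background_metabolic = 100,
    seed = seed
  )
}

# Enzyme-class pool used when decorating planted cluster members.
enzyme_class_pool <- function(has_p450) {
  pool <- c("UDP-glucosyltransferase", "2OG-FeII-oxygenase",
            "O-methyltransferase", "terpene-synthase", "dioxygenase")
  if (has_p450) c("CYP450", pool) else pool
}

#' Generate a synthetic scenario
#'
#' Lays genes on chromosomes (planted cluster members adjacent with ~1-3 kb
#' gaps; background genes separated by 22-40 kb so isolated enzyme genes
#' never chain into spurious runs at the default scan gap), decorates them
#' with enzyme classes, protein families and pathway/reaction annotations,
#' and simulates expression from a latent-factor model:
#' `x_g = loading_g * factor + noise`, shifted by a constant (+8, clipped at
#' zero) to FPKM-like non-negative values. The affine shift preserves every
#' planted Pearson correlation exactly.
#'
#' @param config A [scenario_config()].
#' @return A `scenario` list: `genes` (gene table tibble), `pathways`
#'   (annotation tibble), `expr` ([expr_matrix()]), and `ledger` — the
#'   ground truth (planted clusters with member ids and kinds, module
#'   membership, hub and regulator ids, trait links, seed).
#' @export
simulate_scenario <- function(config) {
  if (!inherits(config, "scenario_config")) abort("`config` must be a scenario_config")
  set.seed(config$seed)
  n_genes <- config$n_genes
  clusters <- config$planted_clusters

  # --- placement -----------------------------------------------------------
  n_cluster_genes <- sum(vapply(clusters, `[[`, integer(1), "size"))
  n_bg <- n_genes - n_cluster_genes
  chrom_of_cluster <- if (length(clusters) > 0) {
    ((seq_along(clusters) - 1L) %% config$n_chroms) + 1L
  } else integer(0)
  bg_per_chrom <- diff(floor(seq(0, n_bg, length.out = config$n_chroms + 1)))

  rows <- list()
  gene_counter <- 0L
  cluster_members <- vector("list", length(clusters))
  for (chrom_i in seq_len(config$n_chroms)) {
    cl_here <- which(chrom_of_cluster == chrom_i)
    n_chunks <- length(cl_here) + 1L
    chunk_sizes <- diff(floor(seq(0, bg_per_chrom[chrom_i], length.out = n_chunks + 1)))
    pos <- 1L
    emit <- function(in_cluster) {
      gene_counter <<- gene_counter + 1L
      len <- round(runif(1, 1000, 3000))
      gap <- if (in_cluster) round(runif(1, 1000, 3000)) else round(runif(1, 22000, 40000))
      row <- list(gene_id = sprintf("g%04d", gene_counter),
                  chrom = sprintf("chr%d", chrom_i),
                  start = pos, end = pos + len,
                  strand = sample(c("+", "-"), 1))
      pos <<- pos + len + gap
      rows[[length(rows) + 1L]] <<- row
      row$gene_id
    }
    for (chunk in seq_len(n_chunks)) {
      for (i in seq_len(chunk_sizes[chunk])) emit(FALSE)
      if (chunk <= length(cl_here)) {
        ci <- cl_here[chunk]
        sz <- clusters[[ci]]$size
        # intra-cluster gaps between members; a background gap after the last
        cluster_members[[ci]] <- vapply(seq_len(sz),
                                        function(i) emit(i < sz), character(1))
      }
    }
  }
  genes <- dplyr::bind_rows(lapply(rows, as_tibble))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$enzyme_classes <- replicate(nrow(genes), character(0), simplify = FALSE)
  genes$family_ids <- replicate(nrow(genes), character(0), simplify = FALSE)
  idx_of <- setNames(seq_len(nrow(genes)), genes$gene_id)

  # --- decorate cluster members -------------------------------------------
  pathway_rows <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    members <- cluster_members[[ci]]
    pool <- enzyme_class_pool(cl$has_p450)
    classes <- pool[((seq_along(members) - 1L) %% cl$n_enzyme_classes) + 1L]
    pwy <- cl$pathway_id %||% sprintf("PWY-%04d", 9000 + ci)
    for (mi in seq_along(members)) {
      gi <- idx_of[[members[mi]]]
      genes$enzyme_classes[[gi]] <- classes[mi]
      genes$family_ids[[gi]] <- if (cl$homologous) sprintf("FAMH-%02d", ci)
                                else sprintf("FAM-%04d", gi)
      pathway_rows[[length(pathway_rows) + 1L]] <- tibble(
        gene_id = members[mi], pathway_id = pwy,
        reaction_id = sprintf("RXN-%04d-%d", 9000 + ci, ((mi - 1L) %% cl$n_reactions) + 1L)
      )
    }
  }

  # --- assign background roles: modules, regulators, metabolic noise ------
  bg_ids <- setdiff(genes$gene_id, unlist(cluster_members))
  bg_ids <- sample(bg_ids)  # scatter roles across the genome
  take <- function(n) {
    out <- bg_ids[seq_len(n)]
    bg_ids <<- bg_ids[-seq_len(n)]
    out
  }
  module_members <- lapply(config$planted_modules, function(m) take(m$size))
  hub_ids <- lapply(seq_along(config$planted_modules), function(i) {
    head(module_members[[i]], config$planted_modules[[i]]$n_hubs)
  })
  regulator_ids <- lapply(config$planted_regulators, function(r) take(r$n))
  metabolic_bg <- take(min(config$n_background_metabolic, length(bg_ids)))
  pool <- enzyme_class_pool(TRUE)
  for (k in seq_along(metabolic_bg)) {
    gi <- idx_of[[metabolic_bg[k]]]
    genes$enzyme_classes[[gi]] <- sample(pool, 1)
    genes$family_ids[[gi]] <- sprintf("FAM-%04d", gi)
    pathway_rows[[length(pathway_rows) + 1L]] <- tibble(
      gene_id = metabolic_bg[k],
      pathway_id = sprintf("PWY-BG%04d", k),
      reaction_id = sprintf("RXN-BG%04d", k)
    )
  }
  pathways <- dplyr::bind_rows(pathway_rows)

  # --- expression ----------------------------------------------------------
  ns <- config$n_samples
  samples <- sample_design(ns)
  cluster_factors <- lapply(clusters, function(cl) rnorm(ns))
  module_factors <- lapply(config$planted_modules, function(m) {
    if (is.null(m$trait_link)) rnorm(ns)
    else m$trait_link$r * cluster_factors[[m$trait_link$cluster]] +
      sqrt(1 - m$trait_link$r^2) * rnorm(ns)
  })

  z <- matrix(rnorm(n_genes * ns, sd = 1), nrow = n_genes,
              dimnames = list(genes$gene_id, samples$sample_id))
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    if (!cl$co_expressed) next  # members keep independent noise profiles
    for (g in cluster_members[[ci]]) {
      loading <- runif(1, cl$loading_range[1], cl$loading_range[2])
      z[g, ] <- loading * cluster_factors[[ci]] + rnorm(ns, sd = config$noise_sd)
    }
  }
  module_loading <- list()
  for (mi in seq_along(config$planted_modules)) {
    m <- config$planted_modules[[mi]]
    for (g in module_members[[mi]]) {
      loading <- if (g %in% hub_ids[[mi]]) m$hub_loading
                 else runif(1, m$loading_range[1], m$loading_range[2])
      module_loading[[g]] <- loading
      z[g, ] <- loading * module_factors[[mi]] + rnorm(ns, sd = config$noise_sd)
    }
  }
  for (ri in seq_along(config$planted_regulators)) {
    r <- config$planted_regulators[[ri]]
    for (g in regulator_ids[[ri]]) {
      z[g, ] <- r$loading * cluster_factors[[r$cluster]] + rnorm(ns, sd = config$noise_sd)
    }
  }
  values <- pmax(z + 8, 0)  # affine shift: non-negative, correlations intact

  ledger <- list(
    seed = config$seed,
    clusters = tibble(
      cluster_id = sprintf("PC%d", seq_along(clusters)),
      kind = vapply(clusters, `[[`, character(1), "kind"),
      pathway_id = vapply(seq_along(clusters), function(ci) {
        clusters[[ci]]$pathway_id %||% sprintf("PWY-%04d", 9000 + ci)
      }, character(1)),
      co_expressed = vapply(clusters, `[[`, logical(1), "co_expressed"),
      gene_ids = cluster_members
    ),
    modules = tibble(
      module_id = sprintf("PM%d", seq_along(config$planted_modules)),
      size = vapply(config$planted_modules, `[[`, integer(1), "size"),
      gene_ids = module_members,
      hub_ids = hub_ids,
      trait_link_cluster = vapply(config$planted_modules, function(m) {
        if (is.null(m$trait_link)) NA_integer_ else as.integer(m$trait_link$cluster)
      }, integer(1)),
      trait_link_r = vapply(config$planted_modules, function(m) {
        if (is.null(m$trait_link)) NA_real_ else m$trait_link$r
      }, double(1))
    ),
    regulators = tibble(
      regulator_ids = regulator_ids,
      cluster = vapply(config$planted_regulators, `[[`, integer(1), "cluster"),
      loading = vapply(config$planted_regulators, `[[`, double(1), "loading")
    ),
    metabolic_background = metabolic_bg
  )

  structure(list(genes = validate_gene_table(genes), pathways = pathways,
                 expr = expr_matrix(values, samples), ledger = ledger,
                 config = config),
            class = "scenario")
}

# 4 time points x 2 conditions x 2 replicates (truncated/recycled to n).
sample_design <- function(n) {
  design <- tidyr::expand_grid(
    timepoint = c("3h", "3d", "7d", "14d"),
    condition = c("mono", "co"),
    replicate = 1:2
  )
  design <- design[rep(seq_len(nrow(design)), length.out = max(n, nrow(design))), ]
  design <- design[seq_len(n), ]
  design$sample_id <- sprintf("%s_%s_r%d", design$condition, design$timepoint,
                              design$replicate)
  design$sample_id <- make.unique(design$sample_id, sep = "_x")
  design[, c("sample_id", "timepoint", "condition", "replicate")]
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d genes, %d samples, %d planted clusters, %d planted modules\n",
              nrow(x$genes), ncol(x$expr$values),
              nrow(x$ledger$clusters), nrow(x$ledger$modules)))
  invisible(x)
}

#' Write a scenario to disk as a fixture bundle
#'
#' Emits the gene table, expression matrix, sample metadata and pathway
#' annotation in the package's TSV dialects plus the ground-truth ledger as
#' JSON — everything re-readable by the package's readers, byte-identical
#' when regenerated from the same seed.
#'
#' @param scenario A [simulate_scenario()] result.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_fixture_bundle <- function(scenario, out_dir) {
  if (!inherits(scenario, "scenario")) abort("`scenario` must come from simulate_scenario()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genes = file.path(out_dir, "genes.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    pathways = file.path(out_dir, "pathways.tsv"),
    ledger = file.path(out_dir, "ledger.json")
  )
  write_report(scenario$genes, paths[["genes"]])
  expr_df <- tibble::as_tibble(scenario$expr$values, rownames = "gene_id")
  write_report(expr_df, paths[["expression"]])
  write_report(scenario$expr$samples, paths[["samples"]])
  write_report(scenario$pathways, paths[["pathways"]])
  ledger <- scenario$ledger
  jsonlite::write_json(ledger, paths[["ledger"]], auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(paths)
}
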