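# End-to-end orchestration: scan -> co-pathway -> co-expression -> network
# -> BGC traits -> hubs/regulators, with recovery scoring against a
# synthetic ground-truth ledger when one is available.

#' Default pipeline configuration
#'
#' One nested list with a section per stage; every threshold of the method
#' is a key with its standard value as default: scan gap 20 kb and 3-10
#' genes, co-expression null at the 95th percentile with pair p < 0.05,
#' module merge at eigengene dissimilarity 0.25 with blocks of at most 8000
#' genes, module-trait significance p < 0.05 and r^2 > 0.5, hub gates
#' MM > 0.8 and GS > 0.2 with the top 30 per module, enrichment p < 1e-4
#' and FDR < 0.05.
#'
#' @param seed Seed used for the null's pair subsampling (the only
#'   stochastic step of the pipeline).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    scan = list(max_gap = 20000, min_genes = 3, max_genes = 10,
                max_intervening = 3),
    copathway = list(per_pathway = TRUE),
    coexpr = list(percentile = 95, min_fraction = 0.5, max_pairs = 2e6,
                  require_significant = TRUE, p_max = 0.05, absolute = FALSE),
    network = list(power = "auto", network_type = "unsigned",
                   merge_cut_height = 0.25, min_module_size = 30,
                   cut_height = "auto", cut_height_cap = 0.85,
                   cut_rescue = c(0.90, 0.95), kme_min = 0.6,
                   max_block_size = 8000, scale_free_fit_target = 0.8),
    trait = list(p_max = 0.05, r2_min = 0.5),
    hubs = list(mm_min = 0.8, gs_min = 0.2, top_k = 30, trait = NULL),
    regulators = list(ids = character(0), high_fraction = 0.5),
    enrich = list(p_max = 1e-4, fdr_max = 0.05)
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @param seed Fallback seed when the file does not set one.
#' @return Nested configuration list.
#' @export
load_config <- function(path, seed = 1) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_config(default_config(seed), user)
}

merge_config <- function(base, user) {
  for (key in names(user)) {
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]])
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Run the full discovery-and-validation pipeline
#'
#' Stages, in order: candidate scan (or external candidate ingestion),
#' structural feature annotation, co-pathway filter, metabolic-pair null and
#' co-expression filter, final validation (co-pathway AND co-expression AND
#' non-homology), network module detection, BGC trait correlation, hub
#' scoring/selection, optional regulator matrices and term enrichment, and
#' — when a ground-truth ledger is supplied — recovery scoring.
#'
#' @param genes Gene table (or omit and pass `scenario`).
#' @param expr Expression matrix.
#' @param pathways Pathway annotation tibble.
#' @param scenario Optional [simulate_scenario()] result supplying genes,
#'   expression, pathways and the ledger at once.
#' @param external_candidates Optional externally predicted candidate tibble
#'   (from [read_external_candidates()]); replaces the scanner.
#' @param terms Optional gene-to-term tibble enabling per-module enrichment.
#' @param config Configuration from [default_config()] / [load_config()].
#' @param ledger Optional ground-truth ledger for recovery scoring.
#' @param out_dir Optional directory; when given, every stage report is
#'   written as TSV plus a `summary.json` (deterministic byte-for-byte for
#'   a fixed config and seed).
#' @return A `run_summary` with stage artifacts in `$artifacts`.
#' @export
run_pipeline <- function(genes = NULL, expr = NULL, pathways = NULL,
                         scenario = NULL, external_candidates = NULL,
                         terms = NULL, config = default_config(),
                         ledger = NULL, out_dir = NULL) {
  if (!is.null(scenario)) {
    genes <- scenario$genes
    expr <- scenario$expr
    pathways <- scenario$pathways
    ledger <- ledger %||% scenario$ledger
  }
  if (is.null(genes) || is.null(expr) || is.null(pathways)) {
    abort("run_pipeline needs genes, expr and pathways (or a scenario)")
  }

  stage <- function(name, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
    log_msg(sprintf("stage %-10s done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  # -- scan ---------------------------------------------------------------
  candidates <- stage("scan", function() {
    cand <- if (!is.null(external_candidates)) external_candidates
    else {
      sc <- config$scan
      scan_clusters(genes, sc$max_gap, sc$min_genes, sc$max_genes,
                    sc$max_intervening) |>
        cluster_features(genes)
    }
    cand
  })
  n_scanned <- nrow(candidates)

  # -- co-pathway ---------------------------------------------------------
  candidates <- stage("copathway", function() {
    filter_copathway(candidates, pathways, config$copathway$per_pathway)
  })
  copathway_report <- attr(candidates, "copathway_report")
  n_copathway <- sum(candidates$copathway_pass)

  # -- co-expression ------------------------------------------------------
  cx <- config$coexpr
  null <- stage("null", function() {
    build_pcc_null(expr, unique(pathways$gene_id), cx$percentile, cx$max_pairs,
                   config$seed, cx$absolute)
  })
  surviving <- candidates[candidates$copathway_pass, , drop = FALSE]
  surviving <- stage("coexpr", function() {
    filter_coexpr(surviving, expr, null, cx$min_fraction,
                  cx$require_significant, cx$p_max)
  })
  coexpr_report <- attr(surviving, "coexpr_report")
  candidates$coexpr_pass <- surviving$coexpr_pass[match(candidates$cluster_id,
                                                        surviving$cluster_id)]
  candidates$validated <- !is.na(candidates$coexpr_pass) & candidates$coexpr_pass &
    candidates$copathway_pass & candidates$nonhomologous
  validated <- candidates[candidates$validated, , drop = FALSE]
  n_validated <- nrow(validated)

  # -- network ------------------------------------------------------------
  net_cfg <- do.call(network_config, config$network)
  modules <- stage("network", function() {
    suppressWarnings(build_modules(expr, net_cfg, keep_adjacency = TRUE))
  })
  adjacency <- modules$adjacency
  modules$adjacency <- NULL

  # -- traits -------------------------------------------------------------
  traits <- stage("traits", function() build_bgc_traits(validated, expr))
  trait_cor <- NULL
  if (ncol(traits$values) > 0 && length(module_labels(modules)) > 0) {
    trait_cor <- stage("traitcor", function() {
      module_trait_correlation(modules, traits, config$trait$p_max,
                               config$trait$r2_min)
    })
  }

  # -- hubs ---------------------------------------------------------------
  records <- NULL
  hubs <- NULL
  if (length(module_labels(modules)) > 0 && !is.null(adjacency)) {
    records <- stage("hubscore", function() {
      score_module_genes(expr, modules, adjacency, traits, config$hubs$trait)
    })
    hubs <- select_hubs(records, config$hubs$mm_min, config$hubs$gs_min,
                        config$hubs$top_k)
  }

  # -- regulators ---------------------------------------------------------
  regulator_results <- NULL
  reg_ids <- config$regulators$ids
  if (length(reg_ids) > 0 && n_validated > 0) {
    regulator_results <- stage("regulators", function() {
      setNames(purrr::map(seq_len(nrow(validated)), function(i) {
        regulator_cluster_matrix(expr, reg_ids, validated$gene_ids[[i]], null,
                                 config$regulators$high_fraction)
      }), validated$cluster_id)
    })
  }

  # -- enrichment ---------------------------------------------------------
  enrichment <- NULL
  if (!is.null(terms)) {
    enrichment <- stage("enrich", function() {
      universe <- rownames(expr_values(expr))
      purrr::map(setNames(nm = module_labels(modules)), function(m) {
        enrich_terms(intersect(module_members(modules, m), universe), universe,
                     terms, config$enrich$p_max, config$enrich$fdr_max)
      })
    })
  }

  # -- scoring ------------------------------------------------------------
  scores <- NULL
  if (!is.null(ledger)) {
    scores <- stage("score", function() {
      score_against_ledger(validated, modules, hubs, ledger)
    })
  }

  sizes <- table(modules$assignment$module[modules$assignment$module != "unassigned"])
  summary <- structure(list(
    funnel = list(scanned = n_scanned, copathway = n_copathway,
                  validated = n_validated),
    n_modules = length(sizes),
    module_size_range = if (length(sizes) > 0) as.integer(range(sizes)) else c(0L, 0L),
    n_unassigned = sum(modules$assignment$module == "unassigned"),
    power = modules$power,
    pcc_threshold = null$threshold,
    n_significant_cells = if (!is.null(trait_cor)) sum(trait_cor$significant) else 0L,
    n_hubs = if (!is.null(hubs)) nrow(hubs) else 0L,
    scores = scores,
    config = config,
    seed = config$seed
  ), class = "run_summary")
  summary$artifacts <- list(candidates = candidates, copathway_report = copathway_report,
                            coexpr_report = coexpr_report, null = null,
                            validated = validated, modules = modules,
                            adjacency = adjacency, traits = traits,
                            trait_cor = trait_cor, records = records, hubs = hubs,
                            regulators = regulator_results,
                            enrichment = enrichment)

  if (!is.null(out_dir)) write_stage_reports(summary, out_dir)
  summary
}

write_stage_reports <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  a <- summary$artifacts
  cand <- a$candidates
  cand$gene_ids <- purrr::map_chr(cand$gene_ids, paste, collapse = ";")
  write_report(cand, file.path(out_dir, "candidates.tsv"))
  write_report(a$copathway_report, file.path(out_dir, "copathway.tsv"))
  write_report(a$coexpr_report, file.path(out_dir, "coexpr.tsv"))
  write_report(tidy(a$modules), file.path(out_dir, "modules.tsv"))
  if (!is.null(a$modules$eigengenes)) {
    me <- tibble::as_tibble(a$modules$eigengenes, rownames = "sample_id")
    write_report(me, file.path(out_dir, "eigengenes.tsv"))
  }
  if (!is.null(a$trait_cor)) {
    write_report(tidy(a$trait_cor), file.path(out_dir, "module_trait.tsv"))
  }
  if (!is.null(a$records)) write_report(a$records, file.path(out_dir, "hub_records.tsv"))
  if (!is.null(a$hubs)) write_report(a$hubs, file.path(out_dir, "hubs.tsv"))
  slim <- summary
  slim$artifacts <- NULL
  write_report(slim, file.path(out_dir, "summary.json"), format = "json")
  invisible(out_dir)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>\n")
  cat(sprintf("  funnel: %d scanned -> %d co-pathway -> %d validated\n",
              x$funnel$scanned, x$funnel$copathway, x$funnel$validated))
  cat(sprintf("  modules: %d (sizes %d-%d), %d unassigned; power %s\n",
              x$n_modules, x$module_size_range[1], x$module_size_range[2],
              x$n_unassigned, as.character(x$power)))
  cat(sprintf("  significant module-trait cells: %d; hubs: %d\n",
              x$n_significant_cells, x$n_hubs))
  if (!is.null(x$scores)) {
    cat(sprintf("  recovery: precision %.2f recall %.2f ARI %.2f hub recall %.2f\n",
                x$scores$cluster_precision, x$scores$cluster_recall,
                x$scores$module_ari, x$scores$hub_recall))
  }
  invisible(x)
}

#' Score pipeline output against a synthetic ground-truth ledger
#'
#' A planted (true) cluster counts as recovered when at least 80% of its
#' members fall inside a single validated candidate; precision is the
#' fraction of validated candidates matching some true planted cluster the
#' same way. Module recovery is the adjusted Rand index between the module
#' assignment and the planted membership (background genes form their own
#' class), and hub recall the fraction of planted hubs present in the
#' selected hub list.
#'
#' @param validated Validated candidate tibble (`cluster_id`, `gene_ids`).
#' @param modules A `module_set`.
#' @param hubs Hub tibble from [select_hubs()] (may be `NULL`).
#' @param ledger Ledger from [simulate_scenario()].
#' @return A list: `cluster_precision`, `cluster_recall`, `module_ari`,
#'   `hub_recall`.
#' @export
score_against_ledger <- function(validated, modules, hubs, ledger) {
  truth <- ledger$clusters
  if (is.null(truth)) abort("ledger lacks planted clusters")
  true_rows <- which(truth$kind == "true")
  overlap_ok <- function(planted, candidate) {
    length(intersect(planted, candidate)) >= 0.8 * length(planted)
  }
  recovered <- vapply(true_rows, function(i) {
    any(vapply(validated$gene_ids, overlap_ok, logical(1),
               planted = truth$gene_ids[[i]]))
  }, logical(1))
  matched <- vapply(validated$gene_ids, function(cand) {
    any(vapply(true_rows, function(i) overlap_ok(truth$gene_ids[[i]], cand),
               logical(1)))
  }, logical(1))
  recall <- if (length(true_rows) > 0) mean(recovered) else NA_real_
  precision <- if (nrow(validated) > 0) mean(matched) else NA_real_

  a <- modules$assignment
  truth_mod <- rep("background", nrow(a))
  names(truth_mod) <- a$gene_id
  for (i in seq_len(nrow(ledger$modules))) {
    ids <- intersect(ledger$modules$gene_ids[[i]], a$gene_id)
    truth_mod[ids] <- ledger$modules$module_id[i]
  }
  ari <- if (nrow(ledger$modules) > 0) {
    adjusted_rand(truth_mod, a$module)
  } else NA_real_

  planted_hubs <- unlist(ledger$modules$hub_ids)
  hub_recall <- if (length(planted_hubs) > 0) {
    if (is.null(hubs) || nrow(hubs) == 0) 0
    else mean(planted_hubs %in% hubs$gene_id)
  } else NA_real_

  list(cluster_precision = precision, cluster_recall = recall,
       module_ari = ari, hub_recall = hub_recall)
}
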