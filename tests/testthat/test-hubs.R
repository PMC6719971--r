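test_that("module membership is the absolute correlation with the eigengene", {
  set.seed(21)
  base <- rnorm(16)
  profiles <- c(lapply(1:5, function(i) base + rnorm(16, sd = 0.01)),
                list(anti = -base + rnorm(16, sd = 0.01)))
  names(profiles) <- c(paste0("g", 1:5), "anti")
  m <- toy_expr(profiles)
  ms <- compute_eigengenes(new_mods(rep("A", 6), names(profiles)), m)
  mm <- module_membership(m, ms)
  expect_true(all(mm > 0.99))  # absolute value: the anti-correlated member too
  expect_named(mm)

  # a gene orthogonal to the eigengene has MM near 0 (exactly 0 in the limit)
  orth <- rnorm(16)
  orth <- orth - sum(orth * ms$eigengenes[, 1]) / sum(ms$eigengenes[, 1]^2) *
    ms$eigengenes[, 1]
  m2 <- toy_expr(c(profiles, list(orth = orth)))
  mm_orth <- module_membership(m2, ms, gene_ids = "orth", module = "M1")
  expect_lt(mm_orth, 0.35)
  expect_error(module_membership(m, ms, gene_ids = "g1", module = "nope"),
               "no eigengene")
})

test_that("gene significance takes absolute correlation with the trait", {
  set.seed(22)
  tr <- rnorm(12)
  m <- toy_expr(list(same = tr, flipped = -tr, noise = rnorm(12)))
  gs <- gene_significance(m, tr)
  expect_equal(unname(gs["same"]), 1, tolerance = 1e-12)
  expect_equal(unname(gs["flipped"]), 1, tolerance = 1e-12)
  expect_lt(gs["noise"], 1)
  expect_error(gene_significance(m, rep(1, 12)), "zero-variance")
})

test_that("null gene significance matches the analytic mean of |r|", {
  # under the null, r has density (1 - r^2)^((n-4)/2) / B(1/2, (n-2)/2),
  # giving E|r| = (2 / (n - 2)) / B(1/2, (n-2)/2); ~0.2095 at n = 16
  n <- 16
  analytic <- (2 / (n - 2)) / beta(0.5, (n - 2) / 2)
  set.seed(23)
  tr <- rnorm(n)
  m <- toy_expr(setNames(lapply(1:400, function(i) rnorm(n)),
                         sprintf("g%03d", 1:400)))
  gs <- gene_significance(m, tr)
  expect_equal(mean(gs), analytic, tolerance = 0.03)
})

test_that("intramodular connectivity sums same-module adjacency", {
  ids <- c("a", "b", "c", "d")
  A <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  diag(A) <- 1
  A["d", ] <- A[, "d"] <- 0  # d disconnected
  A["d", "d"] <- 1
  ms <- new_mods(c("X", "X", "X", "Y"), ids)
  k <- intramodular_connectivity(A, ms, c("a", "b", "c"))
  expect_equal(unname(k), c(1, 1, 1))  # direct summation: 0.5 + 0.5
  expect_equal(unname(intramodular_connectivity(A, ms, "d")), 0)  # singleton

  # adding a zero-adjacency member leaves others unchanged
  ids5 <- c(ids, "e")
  A5 <- rbind(cbind(A, e = 0), e = 0)
  dimnames(A5) <- list(ids5, ids5)
  A5["e", "e"] <- 1
  ms5 <- new_mods(c("X", "X", "X", "Y", "X"), ids5)
  k5 <- intramodular_connectivity(A5, ms5, c("a", "b", "c"))
  expect_equal(unname(k5), unname(k))

  expect_error(intramodular_connectivity(A, new_mods(c("X", "X", "X", "unassigned"),
                                                     ids), "d"),
               "not assigned")
  # oracle cross-check on a random module
  set.seed(24)
  C <- cor(matrix(rnorm(20 * 10), 10, 20))
  Ar <- abs(C)^6
  diag(Ar) <- 1
  dimnames(Ar) <- list(sprintf("r%02d", 1:20), sprintf("r%02d", 1:20))
  msr <- new_mods(rep(c("X", "Y"), each = 10), rownames(Ar))
  kk <- intramodular_connectivity(Ar, msr)
  for (g in names(kk)[c(1, 5, 15)]) {
    members <- msr$assignment$gene_id[msr$assignment$module ==
                                        msr$assignment$module[msr$assignment$gene_id == g]]
    expect_equal(unname(kk[g]), brute_k_within(Ar, members, g), tolerance = 1e-12)
  }
})

test_that("hub selection applies the MM/GS gates and connectivity ranking", {
  records <- tibble::tibble(
    gene_id = c("top", "gated_mm", "gated_gs", "mid", "low"),
    module = "M1",
    MM = c(0.9, 0.7, 0.95, 0.85, 0.81),
    GS = c(0.3, 0.9, 0.1, 0.4, 0.25),
    k_within = c(10, 50, 40, 8, 2))
  hubs <- select_hubs(records, top_k = 2)
  expect_equal(hubs$gene_id, c("top", "mid"))  # gated out despite high k
  expect_equal(hubs$rank, 1:2)

  # truncation: 40 qualifying genes, top 30 kept, deterministic under shuffle
  set.seed(25)
  recs <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40), module = "M1",
    MM = runif(40, 0.81, 0.99), GS = runif(40, 0.21, 0.9),
    k_within = runif(40, 1, 100))
  h1 <- select_hubs(recs, top_k = 30)
  h2 <- select_hubs(recs[sample(40), ], top_k = 30)
  expect_equal(nrow(h1), 30L)
  expect_identical(h1, h2)
  expect_true(all(diff(h1$k_within) <= 0))

  # ties in k_within break by MM then gene id
  tied <- tibble::tibble(gene_id = c("b", "a", "c"), module = "M1",
                         MM = c(0.9, 0.9, 0.95), GS = 0.5, k_within = 5)
  expect_equal(select_hubs(tied, top_k = 2)$gene_id, c("c", "a"))

  none <- select_hubs(records[records$MM > 2, ], top_k = 5)
  expect_equal(nrow(none), 0L)
})

test_that("scored records give hubs with maximal eigengene alignment", {
  set.seed(26)
  f <- rnorm(16)
  profiles <- c(list(hub = 0.98 * f + rnorm(16, sd = 0.05)),
                lapply(1:20, function(i) runif(1, 0.4, 0.7) * f + rnorm(16, sd = 0.3)))
  names(profiles) <- c("hub", sprintf("g%02d", 1:20))
  m <- toy_expr(profiles)
  ms <- compute_eigengenes(new_mods(rep("A", 21), names(profiles)), m)
  adj <- adjacency_matrix(m, 6)
  traits <- matrix(f, 16, 1, dimnames = list(colnames(m), "t"))
  recs <- score_module_genes(m, ms, adj, traits)
  expect_equal(recs$gene_id[which.max(recs$MM)], "hub")
  expect_equal(recs$gene_id[which.max(recs$k_within)], "hub")
})

test_that("regulator-cluster matrices flag planted regulators only", {
  flagged <- logical(20)
  noise_flagged <- logical(20)
  for (s in 1:20) {
    set.seed(s)
    f <- rnorm(16)
    profiles <- c(list(reg = 0.9 * f + rnorm(16, sd = 0.2),
                       noise_reg = rnorm(16)),
                  lapply(1:5, function(i) 0.9 * f + rnorm(16, sd = 0.2)),
                  lapply(1:50, function(i) rnorm(16)))
    names(profiles) <- c("reg", "noise_reg", paste0("c", 1:5), paste0("n", 1:50))
    m <- toy_expr(profiles)
    null <- build_pcc_null(m, paste0("n", 1:50))
    rm_ <- regulator_cluster_matrix(m, c("reg", "noise_reg"), paste0("c", 1:5),
                                    null)
    flagged[s] <- rm_$summary$highly_coexpressed[rm_$summary$regulator == "reg"]
    noise_flagged[s] <- rm_$summary$highly_coexpressed[
      rm_$summary$regulator == "noise_reg"]
  }
  expect_gte(mean(flagged), 0.9)
  expect_lte(mean(noise_flagged), 0.1)
})

test_that("regulator matrix handles identity, absences and empty input", {
  m <- toy_expr(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  rm_ <- regulator_cluster_matrix(m, "a", c("a", "b"))
  expect_equal(rm_$r["a", "a"], 1)
  expect_warning(rm2 <- regulator_cluster_matrix(m, c("a", "zz"), "b"), "absent")
  expect_equal(rownames(rm2$r), "a")
  expect_error(regulator_cluster_matrix(m, character(0), "b"), "empty")
})

test_that("enrichment p-values equal the exact combinatorial tail", {
  set.seed(27)
  for (i in 1:10) {
    N <- sample(40:200, 1)
    universe <- sprintf("u%03d", 1:N)
    module <- sample(universe, sample(5:20, 1))
    K <- sample(5:30, 1)
    term_genes <- sample(universe, K)
    terms <- tibble::tibble(gene_id = term_genes, term_id = "T1")
    res <- enrich_terms(module, universe, terms, p_max = 1, fdr_max = 1)
    k <- length(intersect(module, term_genes))
    if (k == 0) {
      expect_equal(nrow(res), 0L)
    } else {
      expect_equal(res$p, brute_hyper_tail(k, K, N, length(module)),
                   tolerance = 1e-12)
      expect_gte(res$fdr, res$p)
    }
  }
  # the worked configuration: universe 100, module 10, term 10, overlap 5
  universe <- sprintf("u%03d", 1:100)
  module <- universe[1:10]
  terms <- tibble::tibble(gene_id = c(universe[1:5], universe[50:54]),
                          term_id = "T1")
  res <- enrich_terms(module, universe, terms, p_max = 1, fdr_max = 1)
  expect_equal(res$n_term_module, 5L)
  expect_equal(res$p, brute_hyper_tail(5, 10, 100, 10), tolerance = 1e-12)
})

test_that("degenerate enrichment inputs behave as stated", {
  universe <- sprintf("u%02d", 1:50)
  module <- universe[1:10]
  # a term annotating the whole universe has p = 1 and is never kept
  terms_all <- tibble::tibble(gene_id = universe, term_id = "ALL")
  res_all <- enrich_terms(module, universe, terms_all, p_max = 1, fdr_max = 1)
  expect_equal(nrow(res_all), 0L)  # p = 1 can never clear a strict threshold
  expect_equal(attr(res_all, "tested")$p, 1)
  # empty term map
  empty <- tibble::tibble(gene_id = character(0), term_id = character(0))
  expect_equal(nrow(enrich_terms(module, universe, empty)), 0L)
  # module outside the universe
  expect_error(enrich_terms(c(module, "alien"), universe, terms_all),
               "subset")
})
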