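test_that("adjacency follows the soft-threshold power law", {
  C <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  A <- clustermod:::raise_adjacency(C, 6, "unsigned")
  expect_equal(A[1, 2], 0.8^6)      # 0.262144
  expect_equal(A[1, 2], 0.262144)
  C1 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(clustermod:::raise_adjacency(C1, 9, "unsigned")[1, 2], 1)
  C0 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(clustermod:::raise_adjacency(C0, 6, "unsigned")[1, 2], 0)
  # signed transform
  expect_equal(clustermod:::raise_adjacency(C, 2, "signed")[1, 2], 0.81)
})

test_that("zero-variance genes are excluded from the adjacency with a warning", {
  m <- toy_expr(list(a = rnorm(8), b = rnorm(8), flat = rep(2, 8)))
  expect_warning(A <- adjacency_matrix(m, power = 6), "zero-variance")
  expect_equal(rownames(A), c("a", "b"))
})

test_that("TOM reproduces hand-evaluated and limiting cases", {
  # 3 nodes, all off-diagonal 0.5: TOM_12 = (0.25 + 0.5) / (1 + 1 - 0.5)
  A <- matrix(0.5, 3, 3)
  diag(A) <- 1
  tom <- topological_overlap(A)
  expect_equal(tom[1, 2], 0.5)
  # complete graph: TOM = 1 everywhere
  A1 <- matrix(1, 4, 4)
  expect_true(all(topological_overlap(A1) == 1))
  # no edge and no shared neighbourhood: TOM = 0
  A0 <- diag(2)
  expect_equal(topological_overlap(A0)[1, 2], 0)
  expect_error(topological_overlap(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("TOM equals the triple-loop oracle on random adjacencies", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    C <- cor(matrix(rnorm(n * 12), 12, n))
    A <- abs(C)^6
    diag(A) <- 1
    tom <- topological_overlap(A)
    expect_equal(tom, brute_tom(A), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(all(diag(tom) == 1))
  }
})

test_that("two perfect blocks are recovered exactly", {
  set.seed(5)
  f1 <- rnorm(10)
  f2 <- rnorm(10)
  profiles <- c(lapply(1:5, function(i) f1 * (i / 3)),
                lapply(1:5, function(i) f2 * (1 + i / 5)))
  names(profiles) <- paste0("g", 1:10)
  m <- toy_expr(profiles)
  tom <- topological_overlap(adjacency_matrix(m, 6))
  ms <- detect_modules(tom, min_module_size = 3)
  a <- ms$assignment
  expect_equal(length(setdiff(unique(a$module), "unassigned")), 2L)
  expect_equal(length(unique(a$module[1:5])), 1L)
  expect_equal(length(unique(a$module[6:10])), 1L)
})

test_that("fewer genes than the module floor leaves everything unassigned", {
  A <- diag(5)
  expect_warning(ms <- detect_modules(A, min_module_size = 30), "unassigned")
  expect_true(all(ms$assignment$module == "unassigned"))
})

test_that("eigengenes summarise module expression as the first PC over samples", {
  base <- rnorm(12)
  m <- toy_expr(list(a = 2 * base + 1, b = -base, c = base * 5))
  eg <- module_eigengene(m, c("a", "b", "c"))
  expect_equal(eg$var_explained, 1, tolerance = 1e-12)
  # aligned to the mean standardised profile: here 2 of 3 members are
  # positively oriented, so the eigengene tracks +base
  expect_gt(cor(eg$eigengene, base), 0.999)
  expect_equal(sqrt(sum(eg$eigengene^2)), 1, tolerance = 1e-12)

  # anti-correlated halves of equal size: var_explained 1, orientation
  # resolved deterministically
  m2 <- toy_expr(list(a = base, b = -base))
  eg2 <- module_eigengene(m2, c("a", "b"))
  expect_equal(eg2$var_explained, 1, tolerance = 1e-12)
  eg2b <- module_eigengene(m2, c("a", "b"))
  expect_identical(eg2$eigengene, eg2b$eigengene)

  expect_error(module_eigengene(toy_expr(list(a = rep(1, 5), b = rep(2, 5))),
                                c("a", "b")),
               "constant")
})

test_that("eigengenes track a planted factor", {
  cors <- vapply(1:20, function(s) {
    set.seed(s)
    f <- rnorm(16)
    profiles <- lapply(1:40, function(i) 0.9 * f + rnorm(16, sd = 0.2))
    names(profiles) <- paste0("g", 1:40)
    eg <- module_eigengene(toy_expr(profiles), paste0("g", 1:40))
    abs(cor(eg$eigengene, f))
  }, double(1))
  expect_true(all(cors >= 0.95))
})

test_that("module merging follows the eigengene dissimilarity threshold", {
  set.seed(9)
  f1 <- rnorm(40)
  # two modules sharing a factor closely (high ME correlation) -> merged
  p1 <- lapply(1:6, function(i) f1 + rnorm(40, sd = 0.2))
  p2 <- lapply(1:6, function(i) f1 + rnorm(40, sd = 0.2))
  f3 <- rnorm(40)
  p3 <- lapply(1:6, function(i) f3 + rnorm(40, sd = 0.2))
  profiles <- c(p1, p2, p3)
  names(profiles) <- paste0("g", seq_along(profiles))
  m <- toy_expr(profiles)
  ms <- new_mods(c(rep("A", 6), rep("B", 6), rep("C", 6)), names(profiles))
  merged <- merge_close_modules(ms, m, merge_cut_height = 0.25)
  a <- merged$assignment
  expect_equal(a$module[1], a$module[7])    # A and B merged
  expect_false(a$module[1] == a$module[13]) # C stays apart
  expect_equal(length(setdiff(unique(a$module), "unassigned")), 2L)
})

test_that("modules with eigengene correlation below the threshold stay apart", {
  set.seed(10)
  n_s <- 200  # long profiles so empirical ME correlations sit near truth
  z <- rnorm(n_s)
  f1 <- z
  f2 <- 0.70 * z + sqrt(1 - 0.70^2) * rnorm(n_s)  # ME cor ~0.70 < 0.75
  p1 <- lapply(1:5, function(i) f1 + rnorm(n_s, sd = 0.05))
  p2 <- lapply(1:5, function(i) f2 + rnorm(n_s, sd = 0.05))
  profiles <- c(p1, p2)
  names(profiles) <- paste0("g", 1:10)
  m <- toy_expr(profiles)
  ms <- new_mods(c(rep("A", 5), rep("B", 5)), names(profiles))
  merged <- merge_close_modules(ms, m, merge_cut_height = 0.25)
  expect_equal(length(setdiff(unique(merged$assignment$module), "unassigned")), 2L)
})

test_that("module-trait correlation flags the planted relationship", {
  set.seed(12)
  base <- rnorm(16)
  profiles <- lapply(1:6, function(i) base + rnorm(16, sd = 0.05))
  names(profiles) <- paste0("g", 1:6)
  m <- toy_expr(profiles)
  ms <- new_mods(rep("A", 6), names(profiles))
  ms <- compute_eigengenes(ms, m)
  traits <- ms$eigengenes  # trait identical to the eigengene
  colnames(traits) <- "t1"
  res <- module_trait_correlation(ms, traits)
  expect_equal(res$r["M1", "t1"], 1, tolerance = 1e-12)
  expect_true(res$significant["M1", "t1"])

  bad <- traits[16:1, , drop = FALSE]
  expect_error(module_trait_correlation(ms, bad), "misaligned")
})

test_that("orthogonal traits are rarely significant at n = 16", {
  hits <- 0
  n_draws <- 200
  set.seed(13)
  base <- rnorm(16)
  profiles <- lapply(1:6, function(i) base + rnorm(16, sd = 0.1))
  names(profiles) <- paste0("g", 1:6)
  m <- toy_expr(profiles)
  ms <- compute_eigengenes(new_mods(rep("A", 6), names(profiles)), m)
  for (i in seq_len(n_draws)) {
    tr <- matrix(rnorm(16), 16, 1, dimnames = list(rownames(ms$eigengenes), "t"))
    res <- module_trait_correlation(ms, tr)
    hits <- hits + (res$p[1, 1] < 0.05)
  }
  # binomial 95% envelope around 0.05 over 200 draws
  expect_lte(hits / n_draws, 0.05 + 2 * sqrt(0.05 * 0.95 / n_draws))
})

test_that("BGC traits are the member expression rows, with skips warned", {
  m <- toy_expr(list(a = rnorm(8), b = rnorm(8), c = rnorm(8),
                     d = rnorm(8), e = rnorm(8)))
  clusters <- tibble::tibble(cluster_id = "C1",
                             gene_ids = list(c("a", "b", "c", "d", "e")))
  ts <- build_bgc_traits(clusters, m)
  expect_equal(ncol(ts$values), 5L)
  expect_equal(unname(ts$values[, "C1:a"]), unname(m["a", ]))

  clusters2 <- tibble::tibble(cluster_id = "C2", gene_ids = list(c("a", "zz")))
  expect_warning(ts2 <- build_bgc_traits(clusters2, m), "absent")
  expect_equal(ncol(ts2$values), 1L)
})

test_that("soft-threshold selection honours its contracts", {
  set.seed(14)
  # single candidate power is returned unconditionally
  m <- matrix(rnorm(60 * 12), 60, 12, dimnames = list(sprintf("g%02d", 1:60), NULL))
  fit <- suppressWarnings(pick_soft_threshold(m, candidate_powers = 6))
  expect_equal(fit$power, 6)
  expect_equal(nrow(fit$table), 1L)

  # constant matrix is an error
  const <- matrix(1, 60, 12, dimnames = list(sprintf("g%02d", 1:60), NULL))
  expect_error(suppressWarnings(pick_soft_threshold(const)), "constant")

  # all genes perfectly correlated: degenerate fit, warning, a power returned
  base <- rnorm(12)
  perf <- t(vapply(seq(0.5, 3, length.out = 60), function(s) s * base,
                   double(12)))
  rownames(perf) <- sprintf("g%02d", 1:60)
  expect_warning(fitp <- pick_soft_threshold(perf), "fit|degenerate")
  expect_true(fitp$power %in% fitp$table$power)
})

test_that("the fit sweep matches an independent re-computation", {
  set.seed(15)
  f1 <- rnorm(16); f2 <- rnorm(16)
  profiles <- c(lapply(1:40, function(i) 0.8 * f1 + rnorm(16, sd = 0.3)),
                lapply(1:40, function(i) 0.8 * f2 + rnorm(16, sd = 0.3)),
                lapply(1:40, function(i) rnorm(16)))
  names(profiles) <- sprintf("g%03d", seq_along(profiles))
  m <- toy_expr(profiles)
  got <- suppressWarnings(pick_soft_threshold(m, candidate_powers = c(2, 4, 6),
                                              target_fit = 0.8))
  # oracle: recompute the binned regression fit for each power from scratch
  C <- cor(t(m))
  for (row in seq_len(nrow(got$table))) {
    beta <- got$table$power[row]
    A <- abs(C)^beta; diag(A) <- 1
    k <- rowSums(A) - 1
    k <- k[k > 0]
    bins <- cut(log10(k), 10)
    counts <- tapply(k, bins, length)
    mk <- tapply(k, bins, mean)
    keep <- !is.na(counts)
    reg <- lm(log10(counts[keep] / sum(counts[keep])) ~ log10(mk[keep]))
    r2 <- summary(reg)$r.squared
    expected <- if (coef(reg)[2] < 0) r2 else -r2
    expect_equal(got$table$fit[row], expected, tolerance = 1e-10)
  }
})

test_that("block-wise processing reproduces single-block modules on separable data", {
  set.seed(16)
  f1 <- rnorm(16); f2 <- rnorm(16)
  profiles <- c(lapply(1:40, function(i) 0.9 * f1 + rnorm(16, sd = 0.2)),
                lapply(1:40, function(i) 0.9 * f2 + rnorm(16, sd = 0.2)))
  names(profiles) <- sprintf("g%03d", seq_along(profiles))
  m <- toy_expr(profiles)
  whole <- suppressWarnings(build_modules(m, network_config(power = 6, min_module_size = 10)))
  blocked <- suppressWarnings(build_modules(m, network_config(power = 6, min_module_size = 10,
                                                              max_block_size = 50)))
  # blocks may strand a handful of genes whose block separates them from
  # their module; genes assigned in both runs must agree perfectly
  both <- whole$assignment$module != "unassigned" &
    blocked$assignment$module != "unassigned"
  expect_gte(mean(both), 0.9)
  expect_equal(
    clustermod:::adjusted_rand(whole$assignment$module[both],
                               blocked$assignment$module[both]),
    1)
})

test_that("the network stage is deterministic given its inputs", {
  set.seed(17)
  f <- rnorm(16)
  profiles <- c(lapply(1:35, function(i) 0.85 * f + rnorm(16, sd = 0.3)),
                lapply(1:40, function(i) rnorm(16)))
  names(profiles) <- sprintf("g%03d", seq_along(profiles))
  m <- toy_expr(profiles)
  r1 <- suppressWarnings(build_modules(m))
  set.seed(999)  # must not matter
  r2 <- suppressWarnings(build_modules(m))
  expect_identical(r1$assignment, r2$assignment)
  expect_identical(r1$eigengenes, r2$eigengenes)
})
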