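test_that("a tight run of enzyme genes becomes one candidate", {
  genes <- toy_genes(paste0("g", 1:5), "chr1",
                     start = seq(1, by = 2000, length.out = 5),
                     end = seq(1000, by = 2000, length.out = 5),
                     enzyme = "E")
  out <- scan_clusters(genes, max_gap = 10000)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene_ids[[1]], paste0("g", 1:5))
  expect_equal(out$n_genes, 5L)
  expect_equal(out$span_start, 1L)
  expect_equal(out$span_end, 9000L)
})

test_that("isolated enzyme genes and non-enzyme filler do not form candidates", {
  # 3 clustered enzyme genes, 1 enzyme gene 200 kb away, 8 non-enzyme genes
  starts <- c(1000, 3000, 5000,                       # cluster
              seq(20000, by = 20000, length.out = 8), # non-enzyme background
              400000)                                 # lone enzyme gene
  genes <- toy_genes(paste0("g", 1:12), "chr1", starts, starts + 900,
                     enzyme = c("E", "E", "E", rep("", 8), "E"))
  genes <- genes[order(genes$start), ]
  out <- scan_clusters(genes)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene_ids[[1]], c("g1", "g2", "g3"))
  # cross-check against exhaustive enumeration
  oracle <- brute_scan(genes, 20000, 3, 10, 3)
  expect_equal(out$gene_ids, oracle)
})

test_that("no enzyme annotation means no candidates", {
  genes <- toy_genes(paste0("g", 1:6), "chr1",
                     seq(1, by = 5000, length.out = 6),
                     seq(1000, by = 5000, length.out = 6))
  expect_equal(nrow(scan_clusters(genes)), 0L)
})

test_that("scan equals exhaustive enumeration on random small gene tables", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(10:50, 1)
    starts <- cumsum(round(runif(n, 500, 30000)))
    genes <- toy_genes(paste0("g", seq_len(n)), "chr1", starts, starts + 400,
                       enzyme = ifelse(runif(n) < 0.5, "E", ""))
    max_gap <- sample(c(5000, 15000, 25000), 1)
    max_int <- sample(0:3, 1)
    got <- scan_clusters(genes, max_gap, 2, 10, max_int)
    oracle <- brute_scan(genes, max_gap, 2, 10, max_int)
    expect_equal(got$gene_ids, oracle, info = paste("seed", seed))
  }
})

test_that("scanning requires position-sorted input and never re-sorts silently", {
  genes <- toy_genes(c("g1", "g2"), "chr1", c(5000, 1000), c(6000, 2000),
                     enzyme = "E")
  expect_error(scan_clusters(genes), "position-sorted")
})

test_that("structural features capture P450 presence, class diversity and homology", {
  genes <- toy_genes(paste0("g", 1:4), "chr1",
                     seq(1, by = 2000, length.out = 4),
                     seq(1000, by = 2000, length.out = 4),
                     enzyme = c("CYP450", "UDP-glucosyltransferase",
                                "UDP-glucosyltransferase", "2OG-FeII-oxygenase"),
                     family = c("F1", "F2", "F3", "F4"))
  cand <- scan_clusters(genes, min_genes = 3) |> cluster_features(genes)
  # the composition pattern of a quercetin-type cluster: P450s + UDP-GTs + 2OG oxidase
  expect_true(cand$has_p450)
  expect_equal(cand$enzyme_class_count, 3L)
  expect_true(cand$nonhomologous)

  hom <- toy_genes(paste0("h", 1:3), "chr1", c(1, 2000, 4000),
                   c(1000, 3000, 5000), enzyme = "dioxygenase", family = "F1")
  cand2 <- scan_clusters(hom, min_genes = 3) |> cluster_features(hom)
  expect_false(cand2$nonhomologous)
  expect_false(cand2$has_p450)
  expect_equal(cand2$enzyme_class_count, 1L)

  expect_error(
    cluster_features(tibble::tibble(cluster_id = "C1", gene_ids = list("nope")),
                     genes),
    "nope")
})

test_that("P450 synonym matching is case-insensitive", {
  genes <- toy_genes(paste0("g", 1:3), "chr1", c(1, 2000, 4000),
                     c(1000, 3000, 5000),
                     enzyme = c("cytochrome p450 71Z6", "UDP-GT", "UDP-GT"),
                     family = c("F1", "F2", "F3"))
  cand <- scan_clusters(genes, min_genes = 3) |> cluster_features(genes)
  expect_true(cand$has_p450)
})

test_that("scan output is invariant to input row order after sorting", {
  set.seed(42)
  starts <- cumsum(round(runif(30, 500, 25000)))
  genes <- toy_genes(paste0("g", 1:30), "chr1", starts, starts + 400,
                     enzyme = ifelse(runif(30) < 0.5, "E", ""))
  shuffled <- dplyr::arrange(genes[sample(30), ], chrom, start)
  expect_equal(scan_clusters(shuffled)$gene_ids, scan_clusters(genes)$gene_ids)
})

test_that("external candidate lists are ingested, re-sorted, and validated", {
  genes <- toy_genes(paste0("g", 1:6), "chr1",
                     seq(1, by = 2000, length.out = 6),
                     seq(1000, by = 2000, length.out = 6),
                     enzyme = "E", family = paste0("F", 1:6))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cluster_id\tgene_id",
               "ext1\tg2", "ext1\tg1", "ext1\tg3",
               "ext2\tg5", "ext2\tg6"), tsv)
  expect_warning(cand <- read_external_candidates(tsv, genes), "re-sorted")
  expect_equal(nrow(cand), 2L)
  expect_true(all(cand$source == "external"))
  expect_equal(cand$gene_ids[[which(cand$cluster_id == "ext1")]],
               c("g1", "g2", "g3"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cluster_id\tgene_id", "extX\tg1", "extX\tmissing"), bad)
  expect_error(read_external_candidates(bad, genes), "extX.*missing")
})
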