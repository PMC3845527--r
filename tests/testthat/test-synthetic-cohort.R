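test_that("family architecture follows the configured singleton fraction", {
  # degenerate case: everything a singleton
  p <- small_params(n_genes = 300, singleton_fraction = 1)
  ann <- generate_annotation(p)
  expect_equal(nrow(ann$families), 0)
  expect_equal(nrow(ann$genes), 300)

  # multi-copy gene count is binomial around n * (1 - singleton_fraction)
  n <- 10000
  counts <- vapply(1:5, function(s) {
    a <- generate_annotation(sim_params(n_genes = n, n_scaffolds = 12,
                                        singleton_fraction = 0.753, seed = s))
    nrow(a$families)
  }, numeric(1))
  expected <- n * (1 - 0.753)
  se_mean <- sqrt(n * 0.247 * 0.753 / length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se_mean + 2)
})

test_that("annotation geometry is valid and ranks are contiguous", {
  ann <- generate_annotation(small_params())
  g <- ann$genes
  expect_true(all(g$start <= g$end))
  expect_true(all(g$length == g$end - g$start + 1))
  for (sc in unique(g$scaffold)) {
    sub <- g[g$scaffold == sc, ]
    expect_equal(sub$rank, seq_len(nrow(sub)) - 1L)
    if (nrow(sub) > 1)  # non-overlapping along the scaffold
      expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }
  # planted families partition their genes
  expect_equal(anyDuplicated(ann$families$gene_id), 0)
  sizes <- table(ann$families$family_id)
  expect_true(all(sizes >= 2))
  expect_equal(unname(sizes[ann$families$family_id]),
               ann$families$family_size, ignore_attr = TRUE)
})

test_that("tandem families occupy consecutive ranks, scattered ones do not cluster", {
  p <- small_params(n_genes = 2000, seed = 11)
  ann <- generate_annotation(p)
  fam <- merge(ann$families, as.data.frame(ann$genes), by = "gene_id")
  for (fid in unique(fam$family_id[fam$tandem])) {
    sub <- fam[fam$family_id == fid, ]
    expect_equal(length(unique(sub$scaffold)), 1)
    expect_equal(sort(sub$rank), min(sub$rank) + seq_len(nrow(sub)) - 1L)
  }
  # scattered members live on distinct scaffolds where the scaffold count
  # allows it (families larger than that must reuse scaffolds)
  for (fid in unique(fam$family_id[!fam$tandem])) {
    sub <- fam[fam$family_id == fid, ]
    expect_equal(length(unique(sub$scaffold)), min(nrow(sub), 6L))
  }
})

test_that("same seed gives byte-identical cohort files", {
  p <- small_params(n_genes = 400, seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(p, d1)
  simulate_cohort(p, d2)
  for (f in c("genes.gff3", "counts.tsv", "breadth.tsv", "hits.tsv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("deletion truth respects rates, multipliers and reference immunity", {
  p <- small_params(base_del_rate = 0)
  ann <- generate_annotation(p)
  expect_equal(nrow(generate_pav_truth(ann$genes, ann$families, p)), 0)

  # realized multi-copy:singleton rate ratio ~ multiplier over seeds
  del_mc <- 0; del_sg <- 0; n_mc <- 0; n_sg <- 0
  for (s in 1:20) {
    p <- sim_params(n_genes = 5000, n_scaffolds = 10, seed = s,
                    p_tandem = 0, segment_del_prob = 0,
                    base_del_rate = 0.004, multi_copy_multiplier = 5,
                    cluster_multiplier = 2)
    ann <- generate_annotation(p)
    tr <- generate_pav_truth(ann$genes, ann$families, p)
    expect_false(p$reference %in% tr$cultivar)
    is_mc <- tr$gene_id %in% ann$families$gene_id
    del_mc <- del_mc + sum(is_mc); del_sg <- del_sg + sum(!is_mc)
    n_mc <- n_mc + nrow(ann$families) * 4
    n_sg <- n_sg + (5000 - nrow(ann$families)) * 4
  }
  ratio <- (del_mc / n_mc) / (del_sg / n_sg)
  se <- 5 * sqrt(1 / del_mc + 1 / del_sg)
  expect_lt(abs(ratio - 5), 4 * se)
})

test_that("segment deletions extend over gene runs", {
  p <- sim_params(n_genes = 10000, n_scaffolds = 10, seed = 2,
                  segment_del_prob = 1, segment_run_mean = 7)
  ann <- generate_annotation(p)
  tr <- generate_pav_truth(ann$genes, ann$families, p)
  ranks <- ann$genes$rank[match(tr$gene_id, ann$genes$gene_id)]
  scafs <- ann$genes$scaffold[match(tr$gene_id, ann$genes$gene_id)]
  longest <- 0
  for (cv in unique(tr$cultivar)) {
    for (sc in unique(scafs[tr$cultivar == cv])) {
      r <- sort(ranks[tr$cultivar == cv & scafs == sc])
      if (!length(r)) next
      runs <- rle(cumsum(c(1, diff(r) != 1)))$lengths
      longest <- max(longest, runs)
    }
  }
  expect_gte(longest, 7)
})

test_that("count model matches its analytic mean and is linear in retention", {
  # 1,000 identical 1,500 bp genes at x15 with 150 bp reads: lambda = 165
  genes <- gene_table(sprintf("g%04d", 1:1000), "s1",
                      start = (0:999) * 2000 + 1,
                      end = (0:999) * 2000 + 1500)
  p <- sim_params(n_genes = 1000, cultivars = c("R", "A"), reference = "R",
                  depth_per_cultivar = c(R = 15, A = 15), read_len = 150,
                  seed = 5)
  empty <- generate_pav_truth(genes, data.frame(gene_id = character(0)),
                              sim_params(base_del_rate = 0, seed = 1))
  m <- simulate_counts(genes, empty, p)
  lam <- 15 * (1500 + 150) / 150
  expect_lt(abs(mean(m$counts$counts) - lam), 3 * sqrt(lam / 2000))

  # retained fraction 0.5 halves the expectation
  half <- data.frame(gene_id = genes$gene_id, cultivar = "A",
                     kind = "partial", retained_fraction = 0.5)
  m2 <- simulate_counts(genes, half, p)
  expect_lt(abs(mean(m2$counts$counts[, "A"]) - lam / 2),
            3 * sqrt(lam / 2 / 1000))
  # fully deleted, background off: exactly zero counts and breadth
  full <- data.frame(gene_id = genes$gene_id[1], cultivar = "A",
                     kind = "full", retained_fraction = 0)
  p0 <- sim_params(n_genes = 1000, cultivars = c("R", "A"), reference = "R",
                   depth_per_cultivar = c(R = 15, A = 15), breadth_noise = 0,
                   seed = 5)
  m3 <- simulate_counts(genes, full, p0)
  expect_identical(m3$counts$counts[1, "A"], 0L)
  expect_identical(m3$breadth$breadth[1, "A"], 0)
})

test_that("count matrix satisfies its global invariants", {
  p <- small_params(seed = 31)
  ann <- generate_annotation(p)
  tr <- generate_pav_truth(ann$genes, ann$families, p)
  m <- simulate_counts(ann$genes, tr, p)
  expect_true(all(m$counts$counts >= 0))
  expect_true(all(colSums(m$counts$counts) <= m$counts$library_sizes))
  expect_true(all(m$breadth$breadth >= 0 & m$breadth$breadth <= 1))
})

test_that("homology hits cover all family pairs and decoys fail the filters", {
  genes <- gene_table(c("A", "B", "C", "D"), "s1",
                      start = c(1, 3001, 6001, 9001),
                      end = c(1500, 4500, 7500, 10500))
  fams <- data.frame(gene_id = c("A", "B", "C"), family_id = "F_A",
                     family_size = 3L, tandem = TRUE)
  p <- sim_params(n_genes = 4, n_decoys = 0, seed = 8)
  hits <- emit_homology_hits(fams, genes, p)
  expect_gte(nrow(hits), 6)  # all ordered pairs of {A,B,C}
  expect_true(all(hits$evalue <= 1e-20))
  expect_true(all(hits$pident >= 69 & hits$pident <= 100))

  # decoys alone yield no families downstream
  p2 <- small_params(n_genes = 200, singleton_fraction = 1, n_decoys = 150,
                     seed = 3)
  ann <- generate_annotation(p2)
  d <- emit_homology_hits(ann$families, ann$genes, p2)
  expect_gt(nrow(d), 0)
  edges <- filter_hits(d, ann$genes)
  fams2 <- build_families(edges, ann$genes)
  expect_equal(nrow(fams2$families), 0)
  expect_equal(length(fams2$singletons), 200)
})

test_that("planted families are recovered exactly from emitted hits", {
  p <- small_params(n_genes = 1200, seed = 17)
  ann <- generate_annotation(p)
  hits <- emit_homology_hits(ann$families, ann$genes, p)
  edges <- filter_hits(hits, ann$genes)
  rec <- build_families(edges, ann$genes)
  expect_identical(partition_of(rec$families), partition_of(ann$families))
})
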