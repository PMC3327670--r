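test_that("alignment filter keeps unique reads with fewer than two mismatches", {
  reads <- rbind(
    make_reads("chr1", 100L, 136L, mismatches = 0L, is_unique = FALSE),
    make_reads("chr1", 110L, 146L, mismatches = 2L),
    make_reads("chr1", 120L, 156L, mismatches = 1L),
    make_reads("chr1", 130L, 166L, mismatches = 0L),
    make_reads("chrM", 10L, 46L, mismatches = 0L)
  )
  kept <- filter_alignments(reads)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$is_unique & kept$mismatches < 2 &
                    kept$chrom != "chrM"))
  # chrM retained when the filter is off
  expect_equal(nrow(filter_alignments(reads, drop_chrM = FALSE)), 3L)
  # empty input stays empty
  expect_equal(nrow(filter_alignments(reads[0, ])), 0L)
})

test_that("reads are assigned to the largest-overlap exon, once per gene", {
  annot <- tiny_annotation()
  # fully inside A1
  c1 <- count_exon_reads(make_reads("chr1", 120L, 156L), annot)
  expect_equal(unname(c1["A1"]), 1L)
  expect_equal(sum(c1), 1L)
  # overlapping no exon
  expect_equal(sum(count_exon_reads(make_reads("chr1", 10L, 46L), annot)), 0L)
  # spanning A1 (30 bp) and the intron into A2 (6 bp): A1 wins, gene +1
  c2 <- count_exon_reads(make_reads("chr1", 170L, 306L), annot)
  expect_equal(unname(c2["A1"]), 1L)
  expect_equal(unname(c2["A2"]), 0L)
})

test_that("counting agrees with the per-base brute-force oracle", {
  for (seed in 1:5) {
    annot <- random_annotation(n_genes = 6L, seed = seed)
    reads <- with_seed(seed + 100L, {
      start <- sample(0:(max(annot$end) + 50L), 400L, replace = TRUE)
      make_reads("chr1", start, start + 36L)
    })
    got <- count_exon_reads(reads, annot)
    expect_equal(got, naive_exon_counts(reads, annot))
    # each read counts at most once per gene
    gene_counts <- rowsum(as.integer(got), annot$gene_id)
    expect_true(sum(gene_counts) <= 2L * nrow(reads))
  }
})

test_that("count matrices satisfy the gene = sum-of-exons invariant", {
  annot <- tiny_annotation()
  reads <- list(
    s1 = make_reads("chr1", c(120L, 320L, 1010L), c(156L, 356L, 1046L)),
    s2 = make_reads("chr2", c(60L, 100L), c(96L, 136L))
  )
  cm <- count_matrices(reads, annot)
  expect_equal(dim(cm$exon), c(6L, 2L))
  expect_equal(cm$gene, rowsum(cm$exon, annot$gene_id))
  expect_equal(unname(cm$mapped_reads_total), c(3L, 2L))
})

test_that("RPKM follows the exact formula and its invariances", {
  counts <- matrix(c(1000, 0), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  rpkm <- compute_rpkm(counts, c(g1 = 2000, g2 = 500), c(s1 = 1e7))
  expect_identical(rpkm["g1", "s1"], 50)
  expect_identical(rpkm["g2", "s1"], 0)
  # joint rescaling of counts and library size leaves RPKM unchanged
  scaled <- compute_rpkm(counts * 7, c(g1 = 2000, g2 = 500), c(s1 = 7e7))
  expect_equal(scaled, rpkm)
  expect_error(compute_rpkm(counts, c(g1 = 2000, g2 = 500), c(s1 = 0)),
               "empty library")
})

test_that("log-RPKB transform is anchored at zero and monotone", {
  expect_equal(to_log_rpkb(1), log2(1001), tolerance = 1e-12)
  expect_equal(to_log_rpkb(1), 9.9671, tolerance = 1e-4)
  expect_identical(to_log_rpkb(0), 0)
  x <- sort(with_seed(1, stats::runif(50, 0, 100)))
  expect_true(all(diff(to_log_rpkb(x)) > 0))
  expect_error(to_log_rpkb(-1), "non-negative")
})

test_that("expressed-gene sets honour the floor and both modes", {
  rpkm <- rbind(
    gA = c(0.1, 0.3, 2.4),
    gB = c(1.9, 1.9, 1.9),
    gC = c(5, 5, 5)
  )
  colnames(rpkm) <- paste0("sham_", 1:3)
  samples <- data.frame(sample_id = colnames(rpkm), condition = "sham")
  any_rep <- expressed_genes(rpkm, samples, floor = 2)
  expect_setequal(any_rep$sham, c("gA", "gC"))
  grp <- expressed_genes(rpkm, samples, floor = 2, mode = "group_mean")
  expect_setequal(grp$sham, "gC")
  # floor 0 admits everything with any signal
  expect_setequal(expressed_genes(rpkm, samples, floor = 0)$sham,
                  c("gA", "gB", "gC"))
  expect_error(expressed_genes(rpkm, samples, mode = "nope"))
})
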