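test_that("exon RPKM filter keeps exons expressed in either condition", {
  rpkm <- rbind(
    e_low = rep(9.9, 6),
    e_one_side = c(3, 3, 3, 40, 40, 40),
    e_high = rep(50, 6)
  )
  colnames(rpkm) <- c(paste0("sham_", 1:3), paste0("TAC_", 1:3))
  samples <- data.frame(sample_id = colnames(rpkm),
                        condition = rep(c("sham", "TAC"), each = 3))
  contrast <- c(control = "sham", treatment = "TAC")
  expect_setequal(exon_rpkm_filter(rpkm, samples, contrast),
                  c("e_one_side", "e_high"))
  expect_setequal(exon_rpkm_filter(rpkm, samples, contrast, threshold = 0),
                  rownames(rpkm))
})

test_that("contingency tables pool replicates and drop degenerate exons", {
  annot <- exon_annotation(data.frame(
    exon_id = c("e1", "e2", "solo"),
    gene_id = c("gA", "gA", "gB"),
    chrom = "chr1", start = c(0L, 200L, 500L), end = c(100L, 300L, 600L),
    strand = "+", alt_types = ""))
  counts <- rbind(
    e1 = c(10, 12, 8, 30, 28, 32),
    e2 = c(90, 88, 92, 70, 72, 68),
    solo = c(5, 5, 5, 5, 5, 5)
  )
  colnames(counts) <- c(paste0("c", 1:3), paste0("t", 1:3))
  ct <- build_contingency(counts, annot, paste0("c", 1:3), paste0("t", 1:3))
  row <- ct[ct$exon_id == "e1", ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(30, 90, 270, 210))
  # single-exon gene is untestable
  expect_false("solo" %in% ct$exon_id)
  # zero gene reads on one side is a degenerate margin
  counts2 <- counts
  counts2[c("e1", "e2"), 4:6] <- 0
  ct2 <- build_contingency(counts2, annot, paste0("c", 1:3),
                           paste0("t", 1:3))
  expect_false(any(c("e1", "e2") %in% ct2$exon_id))
})

test_that("two-sided Fisher p agrees with the enumeration oracle", {
  expect_identical(fisher_exact(rbind(c(5, 5), c(5, 5))), 1)
  # perfectly discordant table: only the two extreme tables are as extreme
  expect_equal(fisher_exact(rbind(c(10, 0), c(0, 10))),
               2 / choose(20, 10), tolerance = 1e-12)
  # zero margin leaves a single admissible table
  expect_identical(fisher_exact(rbind(c(0, 0), c(7, 3))), 1)
  for (seed in 1:40) {
    tab <- with_seed(seed, matrix(stats::rbinom(4, 15, 0.5), 2))
    p <- fisher_exact(tab)
    expect_equal(p, fisher_oracle_two_sided(tab[1, 1], tab[1, 2],
                                            tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    # the reference implementation agrees too
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # transpose symmetry
    expect_equal(p, fisher_exact(t(tab)), tolerance = 1e-12)
  }
  # upper tail equals the hypergeometric survival function
  tab <- rbind(c(8, 2), c(4, 9))
  expect_equal(fisher_exact(tab, alternative = "greater"),
               stats::phyper(7, 12, 11, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(fisher_exact(rbind(c(-1, 0), c(1, 2))), "non-negative")
})

test_that("sign-error rate: symmetry, extremes, and MC agreement", {
  # symmetric table: both orderings equally likely
  expect_equal(bayes_error_rate(rbind(c(12, 12), c(40, 40))), 0.5,
               tolerance = 1e-6)
  # overwhelming direction
  expect_lt(bayes_error_rate(rbind(c(0, 50), c(50, 0))), 1e-10)
  # moderate table against a high-resolution Monte-Carlo oracle
  tab <- rbind(c(30, 90), c(270, 210))
  e_quad <- bayes_error_rate(tab)
  expect_equal(e_quad, bayes_mc_oracle(tab, 1e6, seed = 7),
               tolerance = 0.01)
  # the packaged MC method is seeded and reproducible
  e_mc1 <- bayes_error_rate(tab, method = "mc", mc_draws = 2e5, seed = 3)
  e_mc2 <- bayes_error_rate(tab, method = "mc", mc_draws = 2e5, seed = 3)
  expect_identical(e_mc1, e_mc2)
  expect_equal(e_quad, e_mc1, tolerance = 0.02)
})

test_that("variant caller applies the Fisher + sign-error + knownAlt cascade", {
  annot <- exon_annotation(data.frame(
    exon_id = c("lab", "unlab", "lab2"),
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1", start = c(0L, 200L, 400L), end = c(100L, 300L, 500L),
    strand = "+",
    alt_types = c("cassetteExon", "", "altPromoter,cassetteExon")))
  tests <- data.frame(
    exon_id = c("lab", "unlab", "lab2"),
    gene_id = c("gA", "gB", "gC"),
    a = c(20, 20, 60), b = c(60, 60, 20),
    c = c(180, 180, 140), d = c(140, 140, 180))
  tests <- test_exon_usage(tests)
  expect_equal(tests$direction, c("inclusion", "inclusion", "exclusion"))
  calls <- call_exon_variants(tests, annot, contrast = "PAH")
  # significant but unlabelled exons are never reported
  expect_setequal(calls$exon_id, c("lab", "lab2"))
  expect_equal(calls$contrast, c("PAH", "PAH"))
  # the sign-error filter can veto a Fisher-significant exon
  tests2 <- tests
  tests2$bayes_e <- c(0.2, 0, 0)
  expect_false("lab" %in% call_exon_variants(tests2, annot)$exon_id)
  # and alpha = 0 vetoes everything
  expect_equal(nrow(call_exon_variants(tests, annot, alpha = 0)), 0L)
})

test_that("variant summaries weight multi-label exons fractionally", {
  calls <- data.frame(
    exon_id = c("e1", "e2", "e3"),
    gene_id = c("g1", "g2", "g3"),
    fisher_p = 0.01, bayes_e = 0.01,
    direction = c("inclusion", "inclusion", "exclusion"),
    alt_types = c("altPromoter", "altPromoter", "altPromoter,cassetteExon"),
    contrast = "PAH", stringsAsFactors = FALSE)
  s <- summarize_variant_types(calls)
  expect_equal(s$directions$inclusion, 2L)
  expect_equal(s$directions$exclusion, 1L)
  tw <- stats::setNames(s$types$weight, s$types$alt_type)
  expect_equal(unname(tw["altPromoter"]), 2.5)
  expect_equal(unname(tw["cassetteExon"]), 0.5)
  expect_equal(sum(s$types$proportion), 1)
  # single-type call lists give a 100% proportion
  mono <- summarize_variant_types(calls[1:2, ])
  expect_equal(mono$types$proportion, 1)
  # empty input gives an empty summary
  empty <- summarize_variant_types(calls[0, ])
  expect_equal(nrow(empty$directions), 0L)
})
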