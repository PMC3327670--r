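test_that("toy annotation is deterministic and loader-compatible", {
  a1 <- build_toy_annotation(n_genes = 40L, seed = 3L)
  a2 <- build_toy_annotation(n_genes = 40L, seed = 3L)
  expect_identical(a1$annotation, a2$annotation)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_false(identical(
    a1$annotation, build_toy_annotation(n_genes = 40L, seed = 4L)$annotation))
  # round-trips through the BED loader
  path <- withr::local_tempfile(fileext = ".bed")
  write_exon_annotation(a1$annotation, path)
  expect_equal(as.data.frame(read_exon_annotation(path)),
               as.data.frame(a1$annotation))
  # genes do not overlap and leave promoter room
  models <- gene_models(a1$annotation)
  for (chrom in unique(models$chrom)) {
    m <- models[models$chrom == chrom, ]
    m <- m[order(m$start), ]
    expect_true(all(diff(m$start) > 0))
    expect_true(all(utils::head(m$end, -1) + 1000 <= utils::tail(m$start, -1)))
  }
  expect_error(build_toy_annotation(n_genes = 5L), ">= 10")
})

test_that("simulated truth respects its structural invariants", {
  ss <- small_sim()
  truth <- ss$sim$truth
  annot <- ss$sim$annotation
  # every spiked exon sits in a multi-exon gene and carries a knownAlt label
  n_ex <- table(annot$gene_id)
  expect_true(all(n_ex[truth$exons$gene_id] >= 3))
  labels <- annot$alt_types[match(truth$exons$exon_id, annot$exon_id)]
  expect_true(all(nzchar(labels)))
  # spike bookkeeping
  tg <- truth$genes
  expect_equal(sum(tg$is_deg_pah), 4L + 1L + 1L)  # regular + on + opposite
  expect_equal(sum(tg$is_turned_on), 1L)
  expect_true(all(tg$dir_pah[tg$is_turned_on] == "up"))
  op <- tg[tg$is_opposite, ]
  expect_true(all(op$dir_pah != op$dir_phh))
  # requesting more spikes than genes fails loudly
  expect_error(
    simulate_experiment(ss$toy$annotation,
                        truth = default_truth_config(n_deg_pah = 100L,
                                                     n_deg_phh = 100L),
                        seed = 1L),
    "more spikes")
})

test_that("materialised reads respect the library-size bookkeeping", {
  ss <- small_sim()
  design <- small_design()
  totals <- vapply(ss$sim$reads, nrow, 0L)
  # per-sample totals fluctuate with the negative-binomial sum, which is
  # wide and right-skewed when a small gene panel concentrates the
  # library; the mean across samples sits near the configured size
  L <- design$library_size[1]
  expect_true(all(abs(totals - L) < 0.3 * L))
  expect_lt(abs(mean(totals) - L), 0.1 * L)
  # decoys are present and removed by the filter
  one <- ss$sim$reads[[1]]
  expect_true(any(!one$is_unique | one$mismatches >= 2))
  kept <- filter_alignments(one)
  expect_true(all(kept$is_unique & kept$mismatches < 2))
  # turned-on genes are silent at baseline (< 2 RPKM in sham)
  cm <- count_matrices(ss$sim$reads, ss$sim$annotation)
  models <- gene_models(ss$sim$annotation)
  rpkm <- compute_rpkm(cm$gene,
                       stats::setNames(models$exon_model_length_bp,
                                       models$gene_id),
                       cm$mapped_reads_total)
  sham <- ss$sim$samples$sample_id[ss$sim$samples$condition == "sham"]
  on_genes <- ss$sim$truth$genes$gene_id[ss$sim$truth$genes$is_turned_on]
  expect_true(all(rowMeans(rpkm[on_genes, sham, drop = FALSE]) < 2))
  tac <- ss$sim$samples$sample_id[ss$sim$samples$condition == "TAC"]
  expect_true(all(rowMeans(rpkm[on_genes, tac, drop = FALSE]) >= 2))
})

test_that("simulation is deterministic and fixtures re-emit byte-identically", {
  toy <- build_toy_annotation(n_genes = 30L, seed = 21L)
  cfg <- default_truth_config(n_deg_pah = 2L, n_deg_phh = 2L,
                              n_turned_on = 1L, n_opposite = 1L,
                              n_as_pah = 2L, n_as_phh = 2L)
  design <- default_design(library_size = 1e4)
  s1 <- simulate_experiment(toy$annotation, design, cfg, seed = 8L)
  s2 <- simulate_experiment(toy$annotation, design, cfg, seed = 8L)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$genes, s2$truth$genes)
  pw <- build_toy_pathways(s1$truth$genes, seed = 9L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_fixture(s1, toy$genome, pw, d1, seed = 8L)
  emit_fixture(s2, toy$genome, pw, d2, seed = 8L)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 5)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # GMT re-parses to the emitted sets
  back <- read_gmt(file.path(d1, "pathways.gmt"))
  expect_equal(back[], pw[], ignore_attr = TRUE)
})

test_that("caller sensitivity rises with effect size", {
  # three fold-change grid points, everything else fixed
  toy <- build_toy_annotation(n_genes = 100L, seed = 31L)
  design <- default_design(library_size = 5e4)
  sens <- vapply(c(1.5, 4, 12), function(fc) {
    cfg <- default_truth_config(n_deg_pah = 10L, n_deg_phh = 0L,
                                n_turned_on = 0L, n_opposite = 0L,
                                n_as_pah = 0L, n_as_phh = 0L,
                                fc_range = c(fc, fc * 1.0001))
    sim <- simulate_experiment(toy$annotation, design, cfg, seed = 32L)
    cm <- count_matrices(sim$reads, sim$annotation)
    models <- gene_models(sim$annotation)
    rpkm <- compute_rpkm(cm$gene,
                         stats::setNames(models$exon_model_length_bp,
                                         models$gene_id),
                         cm$mapped_reads_total)
    sam <- sim$samples
    degs <- call_degs(rpkm,
                      sam$sample_id[sam$condition == "sham"],
                      sam$sample_id[sam$condition == "TAC"])
    spiked <- sim$truth$genes$gene_id[sim$truth$genes$is_deg_pah]
    mean(degs$call[match(spiked, degs$gene_id)] != "ns")
  }, 0)
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], sens[1])
})
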