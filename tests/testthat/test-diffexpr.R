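test_that("pooled t-test matches stats::t.test and handles degeneracy", {
  r <- student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r["t"]), -3.674, tolerance = 1e-3)
  expect_equal(unname(r["p"]), 0.0213, tolerance = 1e-3)
  # random cases against the reference implementation
  for (seed in 1:10) {
    xy <- with_seed(seed, list(x = stats::rnorm(4, 5, 2),
                               y = stats::rnorm(6, 6, 3)))
    mine <- student_t(xy$x, xy$y)
    ref <- stats::t.test(xy$x, xy$y, var.equal = TRUE)
    expect_equal(unname(mine["t"]), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(unname(mine["p"]), ref$p.value, tolerance = 1e-10)
    welch <- student_t(xy$x, xy$y, var_equal = FALSE)
    refw <- stats::t.test(xy$x, xy$y)
    expect_equal(unname(welch["p"]), refw$p.value, tolerance = 1e-10)
  }
  # swapping the groups negates t, p unchanged
  a <- student_t(c(1, 2, 3), c(2, 4, 9))
  b <- student_t(c(2, 4, 9), c(1, 2, 3))
  expect_equal(unname(a["t"]), -unname(b["t"]))
  expect_equal(unname(a["p"]), unname(b["p"]))
  # identical constant groups
  expect_equal(unname(student_t(c(5, 5, 5), c(5, 5, 5))[c("t", "p")]),
               c(0, 1))
  # zero variance, different means: the documented p = 0 limit
  expect_equal(unname(student_t(c(5, 5, 5), c(7, 7, 7))["p"]), 0)
  expect_error(student_t(1, c(1, 2)), "2 replicates")
})

test_that("fold change works on the log-1.5 scale", {
  expect_equal(unname(fold_change(3, 2, pseudocount = 0)),
               c(1.5, 1), tolerance = 1e-12)
  expect_equal(unname(fold_change(4.5, 2, pseudocount = 0)),
               c(2.25, 2), tolerance = 1e-12)
  expect_equal(unname(fold_change(5, 5)), c(1, 0))
  # pseudocount keeps zero denominators finite
  expect_true(is.finite(fold_change(10, 0)[["log15_fc"]]))
  expect_error(fold_change(-1, 2), "non-negative")
})

make_rpkm <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("c", 1:3), paste0("t", 1:3))
  m
}

test_that("DEG caller applies the floor, p and fold-change cascade", {
  rpkm <- make_rpkm(
    up = c(8, 9, 8.5, 30, 31, 29),       # clear induction
    flat = c(10, 11, 10.5, 10.2, 10.8, 11.1),
    low = c(1.0, 1.0, 1.0, 1.8, 1.8, 1.8),  # both means below floor
    down = c(40, 42, 41, 9, 10, 9.5)
  )
  degs <- call_degs(rpkm, paste0("c", 1:3), paste0("t", 1:3))
  expect_s3_class(degs, "deg_table")
  calls <- stats::setNames(degs$call, degs$gene_id)
  expect_equal(unname(calls[c("up", "flat", "down")]),
               c("up", "ns", "down"))
  expect_false(degs$tested[degs$gene_id == "low"])
  expect_equal(calls[["low"]], "ns")
  # the call invariants: up => p < alpha and log15_fc >= 1
  up_rows <- degs[degs$call == "up", ]
  expect_true(all(up_rows$p_value < 0.05 & up_rows$log15_fc >= 1))
  expect_error(call_degs(rpkm, c("c1", "c2", "t1"), paste0("t", 1:3)),
               "overlap")
})

test_that("fold-change filter only removes calls (monotonicity)", {
  sim <- with_seed(42, {
    m <- matrix(stats::rnbinom(200 * 6, mu = 50, size = 10) / 2,
                nrow = 200)
    rownames(m) <- sprintf("g%03d", 1:200)
    colnames(m) <- c(paste0("c", 1:3), paste0("t", 1:3))
    m
  })
  with_fc <- call_degs(sim, paste0("c", 1:3), paste0("t", 1:3))
  no_fc <- call_degs(sim, paste0("c", 1:3), paste0("t", 1:3),
                     min_abs_log15fc = 0)
  expect_true(sum(with_fc$call != "ns") <= sum(no_fc$call != "ns"))
  # every fc-filtered call is also a p-only call
  expect_true(all(with_fc$gene_id[with_fc$call != "ns"] %in%
                    no_fc$gene_id[no_fc$call != "ns"]))
})

test_that("turned-on classifier requires silence outside TAC", {
  rpkm <- rbind(
    on = c(0.4, 0.4, 0.4, 12, 12, 12, 1.1, 1.1, 1.1),
    high_base = c(3, 3, 3, 30, 30, 30, 1, 1, 1),
    loud_ex = c(0.4, 0.4, 0.4, 12, 12, 12, 6, 6, 6)
  )
  colnames(rpkm) <- c(paste0("sham_", 1:3), paste0("TAC_", 1:3),
                      paste0("exercise_", 1:3))
  samples <- data.frame(
    sample_id = colnames(rpkm),
    condition = rep(c("sham", "TAC", "exercise"), each = 3))
  degs <- call_degs(rpkm, paste0("sham_", 1:3), paste0("TAC_", 1:3))
  expect_equal(stats::setNames(degs$call, degs$gene_id),
               c(on = "up", high_base = "up", loud_ex = "up"))
  got <- classify_turned_on(degs, rpkm, samples)
  expect_equal(got, "on")  # baseline or exercise expression disqualifies
  # without exercise data only the sham condition constrains
  no_ex <- samples[samples$condition != "exercise", ]
  got2 <- classify_turned_on(degs, rpkm[, no_ex$sample_id], no_ex)
  expect_setequal(got2, c("on", "loud_ex"))
})

test_that("opposite classifier is sign-symmetric", {
  mk <- function(calls) {
    data.frame(gene_id = names(calls), call = unname(calls),
               stringsAsFactors = FALSE)
  }
  pah <- mk(c(g1 = "up", g2 = "up", g3 = "down", g4 = "up", g5 = "ns"))
  phh <- mk(c(g1 = "down", g2 = "up", g3 = "up", g4 = "ns", g5 = "down"))
  expect_setequal(classify_opposite(pah, phh), c("g1", "g3"))
  expect_setequal(classify_opposite(phh, pah), c("g1", "g3"))
  flagged <- flag_deg_categories(pah, opposite = classify_opposite(pah, phh))
  expect_equal(flagged$opposite, c(TRUE, FALSE, TRUE, FALSE, FALSE))
})
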