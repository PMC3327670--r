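# Hand-built fixtures and independent brute-force oracles shared by the
# test files.  Oracles deliberately avoid the code paths they check.

# --- tiny annotation ------------------------------------------------------

tiny_annotation <- function() {
  exon_annotation(data.frame(
    exon_id = c("A1", "A2", "A3", "B1", "B2", "C1"),
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 300L, 600L, 1000L, 1300L, 50L),
    end = c(200L, 450L, 700L, 1120L, 1400L, 350L),
    strand = c("+", "+", "+", "-", "-", "+"),
    alt_types = c("", "cassetteExon", "", "altPromoter", "", ""),
    stringsAsFactors = FALSE
  ))
}

make_reads <- function(chrom, start, end, mismatches = 0L,
                       is_unique = TRUE) {
  n <- length(start)
  data.frame(
    chrom = rep_len(chrom, n), start = start, end = end,
    read_id = sprintf("r%03d", seq_len(n)),
    mismatches = rep_len(mismatches, n),
    strand = rep_len("+", n),
    is_unique = rep_len(is_unique, n),
    stringsAsFactors = FALSE
  )
}

# random small annotation with possibly overlapping exons within a gene
random_annotation <- function(n_genes, seed) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_genes), function(g) {
      origin <- (g - 1L) * 1200L + sample(0:200, 1L)
      n_ex <- sample(1:4, 1L)
      start <- origin + sort(sample(0:700, n_ex))
      len <- sample(40:250, n_ex, replace = TRUE)
      data.frame(
        exon_id = sprintf("g%02d_e%d", g, seq_len(n_ex)),
        gene_id = sprintf("g%02d", g),
        chrom = "chr1", start = start, end = start + len,
        strand = sample(c("+", "-"), 1L), alt_types = "",
        stringsAsFactors = FALSE
      )
    })
    exon_annotation(do.call(rbind, rows))
  })
}

# --- counting oracle: per-read, per-gene largest-overlap scan -------------

naive_exon_counts <- function(reads, annot) {
  counts <- stats::setNames(integer(nrow(annot)), annot$exon_id)
  for (i in seq_len(nrow(reads))) {
    ov <- pmax(0L, pmin(reads$end[i], annot$end) -
                 pmax(reads$start[i], annot$start))
    ov[annot$chrom != reads$chrom[i]] <- 0L
    for (g in unique(annot$gene_id[ov > 0L])) {
      ix <- which(annot$gene_id == g & ov > 0L)
      best <- ix[order(-ov[ix], annot$start[ix])][1L]
      counts[best] <- counts[best] + 1L
    }
  }
  counts
}

# --- Fisher oracle: enumeration with lchoose-based pmf --------------------

fisher_oracle_pmf <- function(r1, c1, c2) {
  lo <- max(0L, r1 - c2)
  hi <- min(r1, c1)
  x <- lo:hi
  list(x = x,
       p = exp(lchoose(c1, x) + lchoose(c2, r1 - x) - lchoose(c1 + c2, r1)))
}

fisher_oracle_two_sided <- function(a, b, c, d) {
  pmf <- fisher_oracle_pmf(a + b, a + c, b + d)
  p_obs <- pmf$p[pmf$x == a]
  min(1, sum(pmf$p[pmf$p <= p_obs * (1 + 1e-7)]))
}

# --- hypergeometric upper-tail oracle (exact binomial coefficients) -------

hyper_upper_oracle <- function(N, n, M, k) {
  j <- k:min(n, M)
  sum(choose(M, j) * choose(N - M, n - j)) / choose(N, n)
}

# --- Monte-Carlo oracle for the Beta-Binomial sign-error rate -------------

bayes_mc_oracle <- function(tab, n_draws = 1e6, seed = 1) {
  with_seed(seed, {
    th_c <- stats::rbeta(n_draws, tab[1, 1] + 1, tab[2, 1] + 1)
    th_t <- stats::rbeta(n_draws, tab[1, 2] + 1, tab[2, 2] + 1)
    min(mean(th_t > th_c), mean(th_t < th_c))
  })
}

# --- naive IUPAC matcher (position-by-position set membership) ------------

iupac_sets <- function(motif) {
  # a motif N is a wildcard (matches a subject N too); every other code
  # matches only its unambiguous bases, so a subject N never matches it
  map <- c(A = "A", C = "C", G = "G", T = "T",
           M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
           V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGTN")
  lapply(strsplit(motif, "")[[1]], function(l) strsplit(map[[l]], "")[[1]])
}

naive_scan_presence <- function(seq, motif) {
  sets <- iupac_sets(motif)
  m <- length(sets)
  cs <- strsplit(seq, "")[[1]]
  np <- length(cs) - m + 1L
  if (np < 1L) return(FALSE)
  ok <- rep(TRUE, np)
  for (j in seq_len(m)) {
    ok <- ok & cs[seq_len(np) + j - 1L] %in% sets[[j]]
  }
  any(ok)
}

# --- independent reverse complement ---------------------------------------

naive_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  with_seed(seed, paste(sample(alphabet, n, replace = TRUE), collapse = ""))
}

# --- small simulated experiment shared by synthetic/pipeline tests --------

small_truth <- function(...) {
  default_truth_config(n_deg_pah = 4L, n_deg_phh = 4L, n_turned_on = 1L,
                       n_opposite = 1L, n_as_pah = 4L, n_as_phh = 4L, ...)
}

small_design <- function() default_design(library_size = 3e4)

small_sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(small_sim_cache$sim)) {
    toy <- build_toy_annotation(n_genes = 60L, seed = 11L)
    small_sim_cache$toy <- toy
    small_sim_cache$sim <- simulate_experiment(
      toy$annotation, design = small_design(), truth = small_truth(),
      seed = 12L)
  }
  list(toy = small_sim_cache$toy, sim = small_sim_cache$sim)
}
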