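#' Default experimental design of the synthetic generator
#'
#' Four conditions (sham, TAC, sedentary, exercise) with three biological
#' replicates each, mirroring the two-contrast hypertrophy design.
#'
#' @param replicates Replicates per condition (default 3).
#' @param library_size Materialised reads per sample (default 2e5).
#' @return Data frame `sample_id, condition, replicate, library_size`.
#' @export
default_design <- function(replicates = 3L, library_size = 2e5) {
  conds <- conditions_vocab()
  data.frame(
    sample_id = paste0(rep(conds, each = replicates), "_",
                       rep(seq_len(replicates), times = length(conds))),
    condition = rep(conds, each = replicates),
    replicate = rep(seq_len(replicates), times = length(conds)),
    library_size = library_size,
    stringsAsFactors = FALSE
  )
}

#' Default spike configuration of the synthetic generator
#'
#' Defines the ground-truth effects planted in a simulated experiment.
#' Spiked effects are deliberately strong, unambiguous positives: with
#' three biological replicates and negative-binomial dispersion 0.1, the
#' pooled t-test's per-gene power plateaus well below 1 for moderate fold
#' changes, so recovery checks use clear effects rather than borderline
#' ones (see the methods vignette for the power analysis).
#'
#' @param n_deg_pah,n_deg_phh Regular differential-expression spikes per
#'   contrast (half up, half down; fold changes log-uniform on
#'   `fc_range`).
#' @param n_turned_on Turned-on spikes: silent at baseline, strongly
#'   induced in TAC only.
#' @param n_opposite Oppositely regulated spikes: up in one contrast and
#'   down (to near silence) in the other, alternating orientation.
#' @param n_as_pah,n_as_phh Spiked exon-usage events per contrast (half
#'   inclusion, half exclusion).
#' @param fc_range Fold-change range for regular spikes (default
#'   `c(8, 20)`).
#' @param fc_opposite Fold change of opposite spikes (default 30).
#' @param delta_inclusion Inclusion-proportion shift of spiked exons
#'   (default 0.3 from a baseline of 0.5).
#' @param dispersion Negative-binomial dispersion of per-sample gene
#'   counts (default 0.1; per-exon counts inherit the same marginal
#'   dispersion through the multinomial split).
#' @param decoy_fraction Fraction of materialised reads that are decoys
#'   (non-unique or 2-mismatch) exercising the alignment filter (default
#'   0.05).
#' @param baseline_log_mu,baseline_log_sd Log-normal parameters of the
#'   baseline gene abundance distribution.
#' @param turned_on_baseline_rpkm Target baseline RPKM of turned-on genes
#'   (default 0.2, i.e. essentially zero reads at desk scale).
#' @param read_length Read length in bp (default 36, single-end).
#' @return A list of class `truth_config`.
#' @export
default_truth_config <- function(n_deg_pah = 14L, n_deg_phh = 13L,
                                 n_turned_on = 2L, n_opposite = 1L,
                                 n_as_pah = 16L, n_as_phh = 14L,
                                 fc_range = c(8, 20), fc_opposite = 30,
                                 delta_inclusion = 0.3, dispersion = 0.1,
                                 decoy_fraction = 0.05,
                                 baseline_log_mu = log(30),
                                 baseline_log_sd = 1.0,
                                 turned_on_baseline_rpkm = 0.2,
                                 read_length = 36L) {
  structure(list(
    n_deg_pah = n_deg_pah, n_deg_phh = n_deg_phh,
    n_turned_on = n_turned_on, n_opposite = n_opposite,
    n_as_pah = n_as_pah, n_as_phh = n_as_phh,
    fc_range = fc_range, fc_opposite = fc_opposite,
    delta_inclusion = delta_inclusion, dispersion = dispersion,
    decoy_fraction = decoy_fraction,
    baseline_log_mu = baseline_log_mu, baseline_log_sd = baseline_log_sd,
    turned_on_baseline_rpkm = turned_on_baseline_rpkm,
    read_length = read_length
  ), class = "truth_config")
}

#' Zero-effect spike configuration
#'
#' Convenience wrapper for null-calibration experiments: no spiked genes
#' or exons, all other defaults unchanged.
#'
#' @param ... Overrides passed to [default_truth_config()].
#' @return A `truth_config` with every spike count set to zero.
#' @export
null_truth_config <- function(...) {
  default_truth_config(n_deg_pah = 0L, n_deg_phh = 0L, n_turned_on = 0L,
                       n_opposite = 0L, n_as_pah = 0L, n_as_phh = 0L, ...)
}

#' Generate a toy exon annotation and genome
#'
#' Packs non-overlapping genes onto synthetic contigs.  Each gene has
#' 1-12 exons (uniform over `exon_range`) with random exon and intron
#' lengths; roughly `alt_fraction` of exons carry one or two known
#' alternative-splicing labels drawn from the eight-type vocabulary, with
#' label probabilities shaped like the proportions seen in heart splicing
#' surveys (alternative promoters and cassette exons dominating).  Genes
#' are separated by gaps large enough to hold a 1 kb upstream window.
#' Deterministic under `seed`.
#'
#' @param n_genes Number of genes (>= 10; default 300).
#' @param exon_range Range of exons per gene (default `c(1, 12)`).
#' @param alt_fraction Fraction of exons receiving a knownAlt label
#'   (default 0.3).
#' @param n_contigs Number of contigs (default 2).
#' @param seed Integer seed.
#' @param exon_len_range,intron_len_range,gap_range Length ranges in bp.
#' @return List with `annotation` (an [exon_annotation()]) and `genome`
#'   (a `DNAStringSet`).
#' @export
build_toy_annotation <- function(n_genes = 300L, exon_range = c(1L, 12L),
                                 alt_fraction = 0.3, n_contigs = 2L,
                                 seed = 1L,
                                 exon_len_range = c(80L, 400L),
                                 intron_len_range = c(200L, 800L),
                                 gap_range = c(1500L, 3000L)) {
  if (n_genes < 10L) stop("n_genes must be >= 10", call. = FALSE)
  with_seed(seed, {
    type_probs <- c(altPromoter = 0.35, cassetteExon = 0.25,
                    bleedingExon = 0.10, altFinish = 0.08,
                    altThreePrime = 0.07, altFivePrime = 0.07,
                    retainedIntron = 0.05, strangeSplice = 0.03)
    contig <- rep(seq_len(n_contigs), length.out = n_genes)
    rows <- vector("list", n_genes)
    cursor <- setNames(rep(0L, n_contigs), paste0("chr", seq_len(n_contigs)))
    for (g in seq_len(n_genes)) {
      chrom <- paste0("chr", contig[g])
      n_ex <- sample(exon_range[1L]:exon_range[2L], 1L)
      ex_len <- sample(exon_len_range[1L]:exon_len_range[2L], n_ex,
                       replace = TRUE)
      in_len <- if (n_ex > 1L)
        sample(intron_len_range[1L]:intron_len_range[2L], n_ex - 1L,
               replace = TRUE) else integer()
      gap <- sample(gap_range[1L]:gap_range[2L], 1L)
      start <- cursor[[chrom]] + gap
      starts <- start + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ends <- starts + ex_len
      cursor[[chrom]] <- ends[n_ex]
      strand <- sample(c("+", "-"), 1L)
      labelled <- stats::runif(n_ex) < alt_fraction
      alt <- vapply(labelled, function(is_alt) {
        if (!is_alt) return("")
        k <- sample(1:2, 1L, prob = c(0.85, 0.15))
        paste(sample(names(type_probs), k, prob = type_probs),
              collapse = ",")
      }, "")
      gid <- sprintf("gene%03d", g)
      rows[[g]] <- data.frame(
        exon_id = sprintf("%s:e%02d", gid, seq_len(n_ex)),
        gene_id = gid, chrom = chrom, start = starts, end = ends,
        strand = strand, alt_types = alt, stringsAsFactors = FALSE)
    }
    annot <- exon_annotation(do.call(rbind, rows))
    genome <- Biostrings::DNAStringSet(vapply(
      names(cursor), function(chrom) {
        len <- cursor[[chrom]] + max(gap_range)  # tail room past last gene
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
      }, ""))
    list(annotation = annot, genome = genome)
  })
}

#' Plant a consensus motif into upstream windows
#'
#' Overwrites bases inside the 1 kb upstream window of the given genes so
#' that the strand-corrected upstream sequence contains the motif (for
#' `-` genes the reverse complement is written into the genome).  Used to
#' create a motif-positive foreground with known truth.
#'
#' @param genome A `DNAStringSet`.
#' @param models Gene models ([gene_models()]).
#' @param genes Gene ids to receive the motif.
#' @param motif IUPAC-free motif string to plant (default `"GGGAGGG"`).
#' @param offset Distance of the motif start upstream of the TSS in the
#'   strand-corrected window (default 200 bp).
#' @return The modified genome.
#' @export
plant_motif_upstream <- function(genome, models, genes, motif = "GGGAGGG",
                                 offset = 200L) {
  mlen <- nchar(motif)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  for (g in genes) {
    i <- match(g, models$gene_id)
    if (is.na(i)) stop("unknown gene: ", g, call. = FALSE)
    chrom <- models$chrom[i]
    tss <- models$tss[i]
    if (models$strand[i] == "+") {
      from <- tss - offset + 1L          # 1-based start of motif
      Biostrings::subseq(genome[[chrom]], from, from + mlen - 1L) <-
        Biostrings::DNAString(motif)
    } else {
      from <- tss + offset - mlen + 1L
      Biostrings::subseq(genome[[chrom]], from, from + mlen - 1L) <-
        Biostrings::DNAString(rc)
    }
  }
  genome
}

# spiked-gene bookkeeping: choose special genes and per-condition rate
# multipliers; returns the per-gene truth table plus the multiplier matrix
assign_gene_truth <- function(models, truth) {
  n <- nrow(models)
  n_special <- truth$n_deg_pah + truth$n_deg_phh + truth$n_turned_on +
    truth$n_opposite
  if (n_special > n) stop("more spikes requested than genes", call. = FALSE)
  pick <- sample(models$gene_id, n_special)
  take <- function(k) {
    out <- head(pick, k); pick <<- pick[-seq_len(min(k, length(pick)))]; out
  }
  deg_pah <- take(truth$n_deg_pah)
  deg_phh <- take(truth$n_deg_phh)
  turned_on <- take(truth$n_turned_on)
  opposite <- take(truth$n_opposite)

  tt <- data.frame(
    gene_id = models$gene_id,
    is_deg_pah = models$gene_id %in% c(deg_pah, turned_on, opposite),
    is_deg_phh = models$gene_id %in% c(deg_phh, opposite),
    dir_pah = NA_character_, dir_phh = NA_character_,
    true_fc_pah = 1, true_fc_phh = 1,
    is_turned_on = models$gene_id %in% turned_on,
    is_opposite = models$gene_id %in% opposite,
    stringsAsFactors = FALSE
  )
  rownames(tt) <- tt$gene_id

  rfc <- function(k) exp(stats::runif(k, log(truth$fc_range[1L]),
                                      log(truth$fc_range[2L])))
  set_fc <- function(genes, contrast) {
    k <- length(genes)
    if (!k) return()
    up <- rep(c(TRUE, FALSE), length.out = k)
    fc <- ifelse(up, rfc(k), 1 / rfc(k))
    col_fc <- paste0("true_fc_", tolower(contrast))
    col_dir <- paste0("dir_", tolower(contrast))
    tt[genes, col_fc] <<- fc
    tt[genes, col_dir] <<- ifelse(up, "up", "down")
  }
  set_fc(deg_pah, "PAH")
  set_fc(deg_phh, "PHH")
  if (length(turned_on)) {
    tt[turned_on, "true_fc_pah"] <- Inf   # silent -> induced
    tt[turned_on, "dir_pah"] <- "up"
  }
  if (length(opposite)) {
    flip <- rep(c(FALSE, TRUE), length.out = length(opposite))
    tt[opposite, "true_fc_pah"] <- ifelse(flip, 1 / truth$fc_opposite,
                                          truth$fc_opposite)
    tt[opposite, "true_fc_phh"] <- ifelse(flip, truth$fc_opposite,
                                          1 / truth$fc_opposite)
    tt[opposite, "dir_pah"] <- ifelse(flip, "down", "up")
    tt[opposite, "dir_phh"] <- ifelse(flip, "up", "down")
  }
  tt
}

# choose spiked exon-usage events among labelled exons of multi-exon genes
assign_exon_truth <- function(annot, truth, gene_truth) {
  n_ex <- table(annot$gene_id)
  eligible_gene <- names(n_ex)[n_ex >= 3L]
  # keep AS spikes off DE-spiked genes so each signal is clean
  eligible_gene <- setdiff(
    eligible_gene,
    gene_truth$gene_id[gene_truth$is_deg_pah | gene_truth$is_deg_phh])
  # at most one spiked exon per gene so every event has a clean
  # rest-of-gene background; genes need >= 3 exons for that background
  cand <- annot[annot$gene_id %in% eligible_gene, , drop = FALSE]
  idx_by_gene <- split(seq_len(nrow(cand)), cand$gene_id)
  one_per_gene <- vapply(idx_by_gene, function(ix) {
    if (length(ix) == 1L) ix else sample(ix, 1L)
  }, 0L)
  n_as <- truth$n_as_pah + truth$n_as_phh
  if (n_as == 0L) {
    return(data.frame(exon_id = character(), gene_id = character(),
                      is_as_event = logical(), contrast = character(),
                      direction = character(), baseline_inclusion = numeric(),
                      delta_inclusion = numeric(), stringsAsFactors = FALSE))
  }
  if (n_as > length(one_per_gene)) {
    stop("more AS spikes requested than eligible exons", call. = FALSE)
  }
  chosen <- one_per_gene[sample.int(length(one_per_gene), n_as)]
  exon_ids <- cand$exon_id[chosen]
  contrast <- rep(c("PAH", "PHH"), times = c(truth$n_as_pah, truth$n_as_phh))
  direction <- unlist(lapply(c(truth$n_as_pah, truth$n_as_phh), function(k)
    rep(c("inclusion", "exclusion"), length.out = k)), use.names = FALSE)
  data.frame(
    exon_id = exon_ids,
    gene_id = cand$gene_id[chosen],
    is_as_event = TRUE,
    contrast = contrast,
    direction = direction,
    baseline_inclusion = 0.5,
    delta_inclusion = ifelse(direction == "inclusion",
                             truth$delta_inclusion, -truth$delta_inclusion),
    stringsAsFactors = FALSE
  )
}

#' Simulate a spiked two-contrast RNA-Seq experiment
#'
#' Generates per-sample read alignments with known ground truth.  The
#' count model: for each gene and sample the gene read count is drawn
#' negative-binomial with the configured dispersion, and the gene's reads
#' are split across its exons multinomially with weights
#' `exon length x inclusion proportion`.  Through Gamma-Poisson thinning
#' the per-exon marginal counts are then themselves negative-binomial
#' with the same dispersion, while the exon share of the gene stays
#' binomial given the gene count — which keeps the exon-versus-rest
#' Fisher test calibrated under the null.
#'
#' Spiked effects per [default_truth_config()]: regular fold changes
#' applied to the treatment condition of one contrast; turned-on genes
#' silent everywhere except TAC; opposite genes scaled up in one contrast
#' and down in the other; spiked exons (always on labelled exons of
#' multi-exon genes, never on DE-spiked genes) have their inclusion
#' proportion shifted by `delta_inclusion` in the treatment condition.
#' Spiked labelled exons that lack a knownAlt label in the annotation
#' receive one.
#'
#' Expected per-condition totals are normalised to
#' `library_size x (1 - decoy_fraction)` (fixed sequencing depth), and a
#' `decoy_fraction` of additional reads is materialised as non-unique or
#' two-mismatch decoys that the alignment filter must remove.  Reads are
#' fixed-length single-end intervals placed uniformly within their exon.
#'
#' @param annot An [exon_annotation()] (e.g. [build_toy_annotation()]).
#' @param design Design data frame ([default_design()]).
#' @param truth A `truth_config` ([default_truth_config()]).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @return List with elements `reads` (named list of per-sample read data
#'   frames), `samples` (the design), `annotation` (annotation with
#'   spiked-exon labels guaranteed), and `truth` (list of `genes`,
#'   `exons`, `config`).
#' @export
simulate_experiment <- function(annot, design = default_design(),
                                truth = default_truth_config(), seed = 1L) {
  stopifnot(inherits(annot, "exon_annotation"), inherits(truth, "truth_config"))
  with_seed(seed, {
    models <- gene_models(annot)
    gene_truth <- assign_gene_truth(models, truth)
    exon_truth <- assign_exon_truth(annot, truth, gene_truth)

    # guarantee spiked exons carry a knownAlt label
    need <- exon_truth$exon_id[!nzchar(
      annot$alt_types[match(exon_truth$exon_id, annot$exon_id)])]
    if (length(need)) {
      annot$alt_types[match(need, annot$exon_id)] <-
        sample(known_alt_types(), length(need), replace = TRUE,
               prob = c(0.35, 0.25, 0.08, 0.07, 0.07, 0.10, 0.05, 0.03))
    }

    # baseline abundance in arbitrary units; per-condition expected counts
    # are normalised to the target depth, so only ratios matter
    r <- exp(stats::rnorm(nrow(models), truth$baseline_log_mu,
                          truth$baseline_log_sd))
    names(r) <- models$gene_id
    # DE-spiked genes get moderate, comfortably-testable baselines; keeping
    # them off the extreme right tail limits the compositional shift their
    # induction imposes on everyone else under fixed sequencing depth
    strong <- (gene_truth$is_deg_pah | gene_truth$is_deg_phh) &
      !gene_truth$is_turned_on
    r[strong] <- exp(stats::runif(sum(strong), log(8), log(30)))
    len_kb <- setNames(models$exon_model_length_bp / 1000, models$gene_id)
    # abundance-to-realised-RPKM scale at baseline: a gene with abundance r
    # has baseline RPKM of about r * scale once counts are depth-normalised
    scale <- 1e6 / sum(r * len_kb)
    r[gene_truth$is_turned_on] <- truth$turned_on_baseline_rpkm / scale
    contrasts <- default_contrasts()
    cond_mult <- matrix(1, nrow = nrow(models), ncol = 4L,
                        dimnames = list(models$gene_id, conditions_vocab()))
    fc_pah <- ifelse(is.infinite(gene_truth$true_fc_pah), 1,
                     gene_truth$true_fc_pah)
    cond_mult[, "TAC"] <- fc_pah
    cond_mult[, "exercise"] <- gene_truth$true_fc_phh
    # turned-on genes: induced in TAC to the abundance of a strong regular
    # gene, silent everywhere else
    if (any(gene_truth$is_turned_on)) {
      on <- gene_truth$is_turned_on
      induced <- exp(stats::runif(sum(on), log(40), log(100)))
      cond_mult[on, "TAC"] <- induced / r[on]
    }

    # per-exon multinomial weights: length x inclusion proportion;
    # labelled (alternative) exons are partially included at baseline
    ex_w_base <- annot$end - annot$start
    pi_base <- ifelse(nzchar(annot$alt_types), 0.7, 1.0)
    spike_ix <- match(exon_truth$exon_id, annot$exon_id)
    pi_base[spike_ix] <- exon_truth$baseline_inclusion
    ex_w <- list()
    for (cond in conditions_vocab()) {
      pi_cond <- pi_base
      trt_of <- c(TAC = "PAH", exercise = "PHH")
      if (cond %in% names(trt_of)) {
        hit <- exon_truth$contrast == trt_of[[cond]]
        pi_cond[spike_ix[hit]] <- exon_truth$baseline_inclusion[hit] +
          exon_truth$delta_inclusion[hit]
      }
      ex_w[[cond]] <- ex_w_base * pi_cond
    }

    size <- 1 / truth$dispersion
    rl <- truth$read_length
    n_target <- round(design$library_size * (1 - truth$decoy_fraction))
    exon_by_gene <- split(seq_len(nrow(annot)), annot$gene_id)
    stopifnot(identical(names(exon_by_gene), models$gene_id))
    reads <- vector("list", nrow(design))
    names(reads) <- design$sample_id
    genome_max <- tapply(annot$end, annot$chrom, max)

    for (s in seq_len(nrow(design))) {
      cond <- design$condition[s]
      mu_gene <- r * len_kb * cond_mult[, cond]
      mu_gene <- mu_gene / sum(mu_gene) * n_target[s]
      g_counts <- stats::rnbinom(length(mu_gene), mu = mu_gene, size = size)
      exon_counts <- integer(nrow(annot))
      w_cond <- ex_w[[cond]]
      for (gi in seq_along(exon_by_gene)) {
        ix <- exon_by_gene[[gi]]
        cnt <- g_counts[[gi]]
        if (cnt == 0L) next
        exon_counts[ix] <- if (length(ix) == 1L) cnt else
          stats::rmultinom(1L, cnt, w_cond[ix])[, 1L]
      }
      # materialise reads uniformly within their exon
      tot <- sum(exon_counts)
      ex_rep <- rep.int(seq_len(nrow(annot)), exon_counts)
      ex_start <- annot$start[ex_rep]
      ex_len <- (annot$end - annot$start)[ex_rep]
      this_rl <- pmin(rl, ex_len)
      offs <- floor(stats::runif(tot) * (ex_len - this_rl + 1L))
      start <- ex_start + as.integer(offs)
      df <- data.frame(
        chrom = annot$chrom[ex_rep],
        start = start,
        end = start + this_rl,
        read_id = sprintf("%s_r%07d", design$sample_id[s], seq_len(tot)),
        mismatches = sample(0:1, tot, replace = TRUE, prob = c(0.8, 0.2)),
        strand = sample(c("+", "-"), tot, replace = TRUE),
        is_unique = TRUE,
        stringsAsFactors = FALSE
      )
      # decoy reads: removed by the alignment filter
      n_dec <- design$library_size[s] - n_target[s]
      if (n_dec > 0L) {
        dchrom <- sample(names(genome_max), n_dec, replace = TRUE)
        dstart <- floor(stats::runif(n_dec) * (genome_max[dchrom] - rl))
        non_unique <- stats::runif(n_dec) < 0.5
        dec <- data.frame(
          chrom = dchrom,
          start = as.integer(dstart),
          end = as.integer(dstart) + rl,
          read_id = sprintf("%s_d%07d", design$sample_id[s],
                            seq_len(n_dec)),
          mismatches = ifelse(non_unique, sample(0:1, n_dec, replace = TRUE),
                              2L),
          strand = sample(c("+", "-"), n_dec, replace = TRUE),
          is_unique = !non_unique,
          stringsAsFactors = FALSE
        )
        df <- rbind(df, dec)
      }
      rownames(df) <- NULL
      reads[[s]] <- df
    }

    gene_truth$baseline_abundance <- unname(r)
    list(reads = reads, samples = design, annotation = annot,
         truth = list(genes = gene_truth, exons = exon_truth,
                      config = truth))
  })
}

#' Build toy pathway gene sets with one spiked pathway
#'
#' Random pathways over the gene universe plus one spiked pathway composed
#' predominantly of spiked differentially expressed genes, giving a known
#' enrichment target.
#'
#' @param gene_truth Per-gene truth table from [simulate_experiment()].
#' @param n_pathways Number of random pathways (default 20).
#' @param size_range Pathway size range (default `c(10, 40)`).
#' @param seed Integer seed.
#' @return Named list of gene sets; the spiked pathway is named
#'   `"path_spiked"` and recorded in the `"spiked"` attribute.
#' @export
build_toy_pathways <- function(gene_truth, n_pathways = 20L,
                               size_range = c(10L, 40L), seed = 1L) {
  with_seed(seed, {
    genes <- gene_truth$gene_id
    lo <- min(size_range[1L], length(genes))
    hi <- min(size_range[2L], length(genes))
    sets <- lapply(seq_len(n_pathways), function(i) {
      sample(genes, sample(lo:hi, 1L))
    })
    names(sets) <- sprintf("path%02d", seq_len(n_pathways))
    spiked_genes <- gene_truth$gene_id[gene_truth$is_deg_pah]
    filler <- sample(setdiff(genes, spiked_genes),
                     max(3L, round(length(spiked_genes) / 4)))
    sets$path_spiked <- sample(c(spiked_genes, filler))
    attr(sets, "spiked") <- "path_spiked"
    sets
  })
}

#' Build a complete synthetic fixture on disk
#'
#' One-call orchestration of the generator: toy annotation and genome,
#' simulated reads with spiked truth, toy pathways with a spiked pathway,
#' and a motif-planted foreground gene set (the oppositely regulated
#' spikes plus random genes, up to `n_motif_genes`), all emitted via
#' [emit_fixture()].
#'
#' @param dir Output directory.
#' @param n_genes Number of genes (default 300).
#' @param seed Integer seed driving every random choice.
#' @param truth A `truth_config` (default [default_truth_config()]).
#' @param n_motif_genes Size of the motif-planted foreground (default 20).
#' @param motif Motif planted upstream of the foreground genes.
#' @return Invisibly, a list with `dir`, `sim`, `genome`, `pathways`,
#'   `motif_genes`.
#' @export
make_fixture <- function(dir, n_genes = 300L, seed = 1L,
                         truth = default_truth_config(),
                         n_motif_genes = 20L, motif = "GGGAGGG") {
  # distinct sub-seeds so no two components replay the same random stream
  toy <- build_toy_annotation(n_genes = n_genes, seed = seed)
  sim <- simulate_experiment(toy$annotation, truth = truth, seed = seed + 1L)
  pathways <- build_toy_pathways(sim$truth$genes, seed = seed + 2L)
  tg <- sim$truth$genes
  motif_genes <- with_seed(seed + 1000L, {
    base <- tg$gene_id[tg$is_opposite]
    extra <- sample(setdiff(tg$gene_id, base),
                    max(0L, n_motif_genes - length(base)))
    sort(c(base, extra))
  })
  genome <- plant_motif_upstream(toy$genome, gene_models(sim$annotation),
                                 motif_genes, motif = motif)
  emit_fixture(sim, genome, pathways, dir, motif_genes = motif_genes,
               seed = seed)
  invisible(list(dir = dir, sim = sim, genome = genome,
                 pathways = pathways, motif_genes = motif_genes))
}

#' Write a simulated experiment to disk as a pipeline-ready fixture
#'
#' Emits everything [run_all()] consumes — annotation BED, genome FASTA,
#' per-sample read BEDs, sample manifest, GMT pathways, a `fixture.json`
#' pipeline config — plus truth TSVs (test-only; the pipeline never reads
#' them).  All paths inside the manifest and config are relative, and
#' re-emission under the same seed is byte-identical.
#'
#' @param sim Result of [simulate_experiment()].
#' @param genome `DNAStringSet` from [build_toy_annotation()] (possibly
#'   after [plant_motif_upstream()]).
#' @param pathways Named list of gene sets ([build_toy_pathways()]).
#' @param dir Output directory (created if needed).
#' @param motif_genes Optional character vector of motif-planted genes,
#'   written as the truth foreground list.
#' @param seed Seed recorded in `fixture.json`.
#' @return `dir`, invisibly.
#' @export
emit_fixture <- function(sim, genome, pathways, dir, motif_genes = NULL,
                         seed = 1L) {
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  write_exon_annotation(sim$annotation, file.path(dir, "annotation.bed"))
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  manifest <- sim$samples[, c("sample_id", "condition", "replicate")]
  manifest$path <- file.path("reads", paste0(manifest$sample_id, ".bed"))
  for (s in seq_along(sim$reads)) {
    df <- sim$reads[[s]]
    df$is_unique <- as.integer(df$is_unique)
    data.table::fwrite(df, file.path(dir, manifest$path[s]), sep = "\t",
                       quote = FALSE, col.names = FALSE, eol = "\n")
  }
  write_tsv(manifest, file.path(dir, "samples.tsv"))
  write_gmt(pathways, file.path(dir, "pathways.gmt"))
  write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv(sim$truth$exons, file.path(dir, "truth_exons.tsv"))
  if (!is.null(motif_genes)) {
    writeLines(motif_genes, file.path(dir, "truth_motif_genes.txt"))
  }
  cfg <- pipeline_config(
    annotation = "annotation.bed",
    reads_manifest = "samples.tsv",
    genome = "genome.fa",
    gmt = "pathways.gmt",
    seed = seed
  )
  jsonlite::write_json(unclass(cfg), file.path(dir, "fixture.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
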