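#' Read aligned read intervals from a BED-like TSV
#'
#' The pipeline starts from alignment intervals, not raw reads: each row is
#' one aligned read with columns
#' `chrom, start, end, read_id, mismatches, strand` and an optional seventh
#' `is_unique` column (0/1; assumed 1 when absent).  Coordinates are 0-based
#' half-open.
#'
#' @param path Path to the TSV (no header).
#' @return Data frame with columns `chrom, start, end, read_id, mismatches,
#'   strand, is_unique`.
#' @export
read_reads_bed <- function(path) {
  df <- data.table::setDF(data.table::fread(path, sep = "\t", header = FALSE))
  if (!ncol(df) %in% c(6L, 7L)) {
    stop("read BED must have 6 or 7 columns", call. = FALSE)
  }
  if (ncol(df) == 6L) df$V7 <- 1L
  names(df) <- c("chrom", "start", "end", "read_id", "mismatches", "strand",
                 "is_unique")
  df$is_unique <- as.logical(df$is_unique)
  if (any(df$end <= df$start)) stop("reads with end <= start", call. = FALSE)
  df
}

#' Read a per-sample manifest
#'
#' @param path TSV with header and columns
#'   `sample_id, condition, replicate, path` (paths relative to the manifest
#'   location).
#' @return Data frame of the manifest with `path` resolved against the
#'   manifest directory.
#' @export
read_sample_manifest <- function(path) {
  df <- read_tsv(path)
  stopifnot_cols(df, c("sample_id", "condition", "replicate", "path"),
                 "sample manifest")
  df$path <- file.path(dirname(path), df$path)
  df
}

#' Filter read alignments
#'
#' Keeps only uniquely mapped reads with fewer than two mismatches, and
#' (by default) drops reads on the mitochondrial chromosome, for which no
#' gene annotation is carried.  The per-sample mapped-read total used as the
#' RPKM normaliser is the number of reads *surviving* this filter.
#'
#' @param reads Data frame as returned by [read_reads_bed()].
#' @param max_mismatches Reads with `mismatches >= max_mismatches` are
#'   dropped (default 2, i.e. "fewer than two mismatches").
#' @param drop_chrM Drop reads on the mitochondrial chromosome?  Default
#'   `TRUE`.
#' @param chrM_name Name of the mitochondrial chromosome (default "chrM").
#' @return The filtered data frame.  An empty input (or one where every read
#'   is filtered) yields an empty data frame.
#' @export
filter_alignments <- function(reads, max_mismatches = 2L, drop_chrM = TRUE,
                              chrM_name = "chrM") {
  stopifnot_cols(reads, c("chrom", "start", "end", "mismatches", "is_unique"),
                 "reads")
  keep <- reads$is_unique & reads$mismatches < max_mismatches
  if (drop_chrM) keep <- keep & reads$chrom != chrM_name
  reads[keep, , drop = FALSE]
}

#' Count reads per exon for one sample
#'
#' Each read increments exactly one exon per gene: among the exons of a gene
#' it overlaps, the one with the largest base-pair overlap (ties broken
#' toward the exon with the smaller start coordinate).  Reads overlapping no
#' exon are not counted.  A read overlapping exons of two different genes
#' counts once in each gene.  The gene count is by construction the sum of
#' the gene's exon counts.
#'
#' Strand is ignored during assignment (unstranded library chemistry).
#'
#' @param reads Filtered read data frame ([filter_alignments()]).
#' @param annot An [exon_annotation()].
#' @return Integer vector of exon counts, named by `exon_id`, in annotation
#'   order.
#' @export
count_exon_reads <- function(reads, annot) {
  stopifnot(inherits(annot, "exon_annotation"))
  counts <- setNames(integer(nrow(annot)), annot$exon_id)
  if (nrow(reads) == 0L) return(counts)
  gr_reads <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end))
  gr_ex <- annotation_granges(annot)
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_ex, ignore.strand = TRUE)
  if (length(hits) == 0L) return(counts)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(GenomicRanges::pintersect(gr_reads[q], gr_ex[s]))
  dt <- data.table::data.table(
    read = q, exon = s, gene = annot$gene_id[s], ov = ov,
    exon_start = annot$start[s])
  # largest overlap wins within (read, gene); tie -> smaller exon start
  data.table::setorderv(dt, c("read", "gene", "ov", "exon_start"),
                        order = c(1L, 1L, -1L, 1L))
  dt <- dt[!duplicated(dt, by = c("read", "gene"))]
  tab <- dt[, .N, by = "exon"]
  counts[tab$exon] <- tab$N
  counts
}

#' Exon- and gene-level count matrices across samples
#'
#' Applies [filter_alignments()] and [count_exon_reads()] to every sample
#' and assembles the results.
#'
#' @param reads_by_sample Named list of read data frames, one per sample.
#' @param annot An [exon_annotation()].
#' @param filter Apply [filter_alignments()] first?  Default `TRUE`.
#' @param ... Passed to [filter_alignments()].
#' @return List with elements
#'   `exon` (integer matrix exons x samples), `gene` (integer matrix genes x
#'   samples, each gene the sum of its exon rows), and `mapped_reads_total`
#'   (named integer vector of post-filter library sizes).
#' @export
count_matrices <- function(reads_by_sample, annot, filter = TRUE, ...) {
  stopifnot(is.list(reads_by_sample), !is.null(names(reads_by_sample)))
  if (filter) {
    reads_by_sample <- lapply(reads_by_sample, filter_alignments, ...)
  }
  exon <- vapply(reads_by_sample, count_exon_reads, annot = annot,
                 FUN.VALUE = integer(nrow(annot)))
  if (is.null(dim(exon))) exon <- matrix(exon, nrow = nrow(annot))
  dimnames(exon) <- list(annot$exon_id, names(reads_by_sample))
  gene <- rowsum(exon, group = annot$gene_id)
  mapped <- vapply(reads_by_sample, nrow, 0L)
  list(exon = exon, gene = gene, mapped_reads_total = mapped)
}

#' RPKM expression matrix
#'
#' RPKM is reads per kilobase of exon model per million mapped reads:
#' `RPKM[i, s] = counts[i, s] / (length_kb[i] * mapped[s] / 1e6)`.
#' For exon rows the exon length is used; for gene rows the exon-model
#' (merged exon union) length.
#'
#' @param counts Count matrix (features x samples).
#' @param lengths_bp Feature lengths in base pairs, in row order or named by
#'   row name.
#' @param mapped_reads_total Post-filter mapped reads per sample, in column
#'   order or named by column name.
#' @return Numeric matrix of RPKM values with the dimnames of `counts`.
#' @export
compute_rpkm <- function(counts, lengths_bp, mapped_reads_total) {
  if (!is.null(names(lengths_bp)) && !is.null(rownames(counts))) {
    lengths_bp <- lengths_bp[rownames(counts)]
  }
  if (!is.null(names(mapped_reads_total)) && !is.null(colnames(counts))) {
    mapped_reads_total <- mapped_reads_total[colnames(counts)]
  }
  if (length(lengths_bp) != nrow(counts)) {
    stop("lengths_bp must match rows of counts", call. = FALSE)
  }
  if (length(mapped_reads_total) != ncol(counts)) {
    stop("mapped_reads_total must match columns of counts", call. = FALSE)
  }
  if (any(lengths_bp <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  if (any(mapped_reads_total <= 0)) {
    stop("empty library: mapped_reads_total must be > 0 for every sample",
         call. = FALSE)
  }
  sweep(counts / (lengths_bp / 1000), 2L, mapped_reads_total / 1e6, "/")
}

#' Log2 RPKB transform
#'
#' RPKB (reads per kilobase per billion mapped reads) is `1000 * RPKM`; the
#' log view is `log2(1000 * RPKM + pseudocount)`.  With the default
#' pseudocount of 1, zero counts map to 0.
#'
#' @param rpkm RPKM matrix or vector (non-negative).
#' @param pseudocount Added before the log (default 1).
#' @return `log2(1000 * rpkm + pseudocount)`.
#' @export
to_log_rpkb <- function(rpkm, pseudocount = 1) {
  if (any(rpkm < 0)) stop("RPKM values must be non-negative", call. = FALSE)
  log2(1000 * rpkm + pseudocount)
}

#' Per-condition expressed-gene sets
#'
#' A gene is called expressed in a condition when its RPKM reaches `floor`
#' either in at least one replicate (`mode = "any_replicate"`, the default)
#' or in the condition mean (`mode = "group_mean"`).
#'
#' @param rpkm Gene-level RPKM matrix (genes x samples).
#' @param samples Sample manifest data frame (`sample_id`, `condition`).
#' @param floor Expression floor in RPKM (default 2).
#' @param mode `"any_replicate"` or `"group_mean"`.
#' @return Named list (one element per condition) of expressed gene-id sets.
#' @export
expressed_genes <- function(rpkm, samples, floor = 2,
                            mode = c("any_replicate", "group_mean")) {
  mode <- match.arg(mode)
  conds <- unique(samples$condition)
  out <- lapply(conds, function(cond) {
    cols <- samples_for(samples, cond)
    sub <- rpkm[, cols, drop = FALSE]
    ok <- if (mode == "any_replicate") {
      apply(sub >= floor, 1L, any)
    } else {
      rowMeans(sub) >= floor
    }
    rownames(rpkm)[ok]
  })
  names(out) <- conds
  out
}
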