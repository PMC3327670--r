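#' Extract strand-aware upstream promoter sequences
#'
#' For every gene the `length` bases immediately upstream of the
#' transcription start site are extracted, strand-corrected so that the
#' last base of the returned sequence abuts the TSS: for `+` genes the
#' genomic window `[tss - length, tss)`, for `-` genes the reverse
#' complement of `[tss, tss + length)` (0-based half-open).  Windows are
#' clipped at contig ends; genes whose window is empty after clipping are
#' dropped.
#'
#' @param models Gene models from [gene_models()].
#' @param genome A [Biostrings::DNAStringSet] named by chromosome, or the
#'   path to a FASTA file.
#' @param length Upstream window size in bp (default 1000).
#' @return A `DNAStringSet` named by `gene_id`, uppercase.
#' @export
extract_upstream <- function(models, genome, length = 1000) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(models$chrom), names(genome))
  if (base::length(missing)) {
    stop("chromosome(s) absent from FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  widths <- setNames(Biostrings::width(genome), names(genome))
  seqs <- vector("list", nrow(models))
  keep <- logical(nrow(models))
  for (i in seq_len(nrow(models))) {
    chrom <- models$chrom[i]
    tss <- models$tss[i]
    if (models$strand[i] == "+") {
      from <- max(1L, tss - length + 1L)  # 1-based
      to <- tss                            # base before the TSS
    } else {
      from <- tss + 1L
      to <- min(widths[[chrom]], tss + length)
    }
    if (to < from) next
    s <- Biostrings::subseq(genome[[chrom]], from, to)
    if (models$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[[i]] <- s
    keep[i] <- TRUE
  }
  out <- Biostrings::DNAStringSet(seqs[keep])
  names(out) <- models$gene_id[keep]
  out
}

check_iupac <- function(motif) {
  if (!nzchar(motif)) stop("empty motif", call. = FALSE)
  letters_ok <- strsplit(motif, "")[[1L]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(letters_ok)) {
    stop("motif contains non-IUPAC letters", call. = FALSE)
  }
  invisible(motif)
}

#' Scan upstream sequences for a consensus motif
#'
#' Presence/absence per sequence under the occurrence rules used for
#' promoter consensus motifs: an exact IUPAC match on the given strand
#' only (the reverse complement is *not* considered), counted at most once
#' per upstream however many times it occurs.  IUPAC ambiguity codes in
#' the motif are interpreted; an `N` in the sequence is literal and never
#' matches a non-N motif letter.
#'
#' @param seqs A `DNAStringSet` (e.g. from [extract_upstream()]) or a
#'   character vector of sequences.
#' @param motif IUPAC consensus string, e.g. `"GGGAGGG"`.
#' @return Named logical vector: does the motif occur in each sequence?
#' @export
scan_presence <- function(seqs, motif) {
  check_iupac(motif)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vcountPattern(motif, seqs, fixed = "subject") > 0
  setNames(hits, names(seqs))
}

#' Consensus-motif enrichment in a foreground gene set
#'
#' Compares motif occurrence between a foreground gene set and a disjoint
#' background set with a one-sided Fisher exact test (upper tail:
#' over-representation in the foreground) on the 2x2 presence table.
#'
#' @param foreground,background Disjoint character vectors of gene ids;
#'   both must be present among `names(seqs)`.
#' @param seqs Named `DNAStringSet` of upstream sequences.
#' @param motif IUPAC consensus string.
#' @return One-row data frame: `motif, fg_hit, fg_total, bg_hit, bg_total,
#'   p`.
#' @export
motif_enrichment <- function(foreground, background, seqs, motif) {
  if (!length(foreground)) stop("empty foreground", call. = FALSE)
  if (length(intersect(foreground, background))) {
    stop("foreground and background overlap", call. = FALSE)
  }
  miss <- setdiff(c(foreground, background), names(seqs))
  if (length(miss)) {
    stop("genes without upstream sequence: ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  hit <- scan_presence(seqs, motif)
  fg_hit <- sum(hit[foreground]); bg_hit <- sum(hit[background])
  fg_total <- length(foreground); bg_total <- length(background)
  tab <- rbind(c(fg_hit, fg_total - fg_hit),
               c(bg_hit, bg_total - bg_hit))
  data.frame(motif = motif, fg_hit = fg_hit, fg_total = fg_total,
             bg_hit = bg_hit, bg_total = bg_total,
             p = fisher_exact(tab, alternative = "greater"),
             stringsAsFactors = FALSE)
}
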