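#' Read an exon annotation
#'
#' The annotation is the universe the whole pipeline works on: one row per
#' exon, with gene membership and (optionally) known alternative-splicing
#' type labels.  Two input flavours are supported:
#'
#' * `format = "bed"` — a BED-like TSV with columns
#'   `chrom, start, end, exon_id, gene_id, strand, alt_types`
#'   (0-based half-open coordinates; `alt_types` a comma-separated list of
#'   labels from [known_alt_types()], empty for constitutive exons; the
#'   seventh column may be omitted).
#' * `format = "gtf"` — a GTF/GFF-like file whose `exon` features carry
#'   `gene_id` (and optionally `exon_id`) attributes.  GTF 1-based closed
#'   coordinates are converted to the internal 0-based half-open convention
#'   on read.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` (default) or `"gtf"`.
#' @return A `data.frame` of class `exon_annotation` with columns
#'   `exon_id, gene_id, chrom, start, end, strand, alt_types`.
#' @export
read_exon_annotation <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- data.table::setDF(data.table::fread(path, sep = "\t", header = FALSE))
    if (ncol(df) == 6L) df$V7 <- ""
    if (ncol(df) != 7L) {
      stop("BED-like annotation must have 6 or 7 columns", call. = FALSE)
    }
    names(df) <- c("chrom", "start", "end", "exon_id", "gene_id", "strand",
                   "alt_types")
    df$alt_types[is.na(df$alt_types)] <- ""
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF annotations requires the rtracklayer package",
           call. = FALSE)
    }
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    md <- S4Vectors::mcols(gr)
    exon_id <- if ("exon_id" %in% names(md)) as.character(md$exon_id) else
      paste0(md$gene_id, ":", seq_along(gr))
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # GTF is 1-based closed
      end = GenomicRanges::end(gr),
      exon_id = exon_id,
      gene_id = as.character(md$gene_id),
      strand = as.character(GenomicRanges::strand(gr)),
      alt_types = "",
      stringsAsFactors = FALSE
    )
  }
  exon_annotation(df)
}

#' Construct and validate an exon annotation
#'
#' @param df Data frame with columns
#'   `exon_id, gene_id, chrom, start, end, strand, alt_types`.
#' @return The validated data frame with class `exon_annotation`.
#' @export
exon_annotation <- function(df) {
  stopifnot_cols(df, c("exon_id", "gene_id", "chrom", "start", "end",
                       "strand", "alt_types"), "annotation")
  df <- as.data.frame(df)[, c("exon_id", "gene_id", "chrom", "start", "end",
                              "strand", "alt_types")]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$alt_types <- as.character(df$alt_types)
  df$alt_types[is.na(df$alt_types)] <- ""
  if (any(df$end <= df$start)) {
    stop("annotation has exons with end <= start", call. = FALSE)
  }
  if (anyDuplicated(df$exon_id)) {
    stop("exon_id values must be unique within the annotation", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("exon strand must be '+' or '-'", call. = FALSE)
  }
  bad <- setdiff(unlist(alt_types_list(df)), known_alt_types())
  if (length(bad)) {
    stop("unknown alt_types label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  per_gene <- tapply(paste(df$chrom, df$strand),
                     df$gene_id, function(x) length(unique(x)))
  if (any(per_gene > 1L)) {
    stop("all exons of a gene must share chrom and strand", call. = FALSE)
  }
  class(df) <- c("exon_annotation", "data.frame")
  df
}

# alt_types as a list of character vectors (character(0) for constitutive)
alt_types_list <- function(annot) {
  lapply(strsplit(annot$alt_types, ",", fixed = TRUE),
         function(x) x[nzchar(x)])
}

#' Label exons with known alternative-splicing types from a second BED
#'
#' Alternative to carrying labels in the annotation itself: a knownAlt-style
#' BED (`chrom, start, end, type`) is intersected with the exons by
#' coordinates, and the type of every overlapping feature is appended to the
#' exon's `alt_types`.
#'
#' @param annot An [exon_annotation()].
#' @param alt A data frame with columns `chrom, start, end, type`
#'   (0-based half-open), or a path to such a TSV (no header).
#' @return The annotation with updated `alt_types`.
#' @export
apply_known_alt <- function(annot, alt) {
  if (is.character(alt)) {
    alt <- data.table::setDF(data.table::fread(alt, sep = "\t", header = FALSE))
    names(alt) <- c("chrom", "start", "end", "type")[seq_len(ncol(alt))]
  }
  stopifnot_cols(alt, c("chrom", "start", "end", "type"), "knownAlt BED")
  gr_ex <- annotation_granges(annot)
  gr_alt <- GenomicRanges::GRanges(
    alt$chrom, IRanges::IRanges(alt$start + 1L, alt$end))
  hits <- GenomicRanges::findOverlaps(gr_ex, gr_alt, ignore.strand = TRUE)
  cur <- alt_types_list(annot)
  for (i in seq_along(hits)) {
    q <- S4Vectors::queryHits(hits)[i]
    cur[[q]] <- union(cur[[q]], alt$type[S4Vectors::subjectHits(hits)[i]])
  }
  annot$alt_types <- vapply(cur, paste, "", collapse = ",")
  exon_annotation(annot)
}

annotation_granges <- function(annot) {
  GenomicRanges::GRanges(
    annot$chrom,
    IRanges::IRanges(annot$start + 1L, annot$end),  # to 1-based closed
    strand = annot$strand
  )
}

#' Derive gene models from an exon annotation
#'
#' A gene model is the union of a gene's exon intervals.  Its length (the
#' "exon model" length) is the RPKM denominator, and the transcription start
#' site is the strand-aware 5' end of the union.
#'
#' @param annot An [exon_annotation()].
#' @return Data frame with one row per gene: `gene_id, chrom, strand, tss,
#'   exon_model_length_bp, n_exons, start, end`.  `tss` is a 0-based
#'   coordinate: for `+` genes the smallest exon start, for `-` genes the
#'   largest exon end.
#' @export
gene_models <- function(annot) {
  stopifnot(inherits(annot, "exon_annotation"))
  sp <- split(seq_len(nrow(annot)), annot$gene_id)
  res <- lapply(sp, function(idx) {
    ir <- IRanges::IRanges(annot$start[idx] + 1L, annot$end[idx])
    merged <- IRanges::reduce(ir)
    s <- annot$strand[idx[1L]]
    data.frame(
      gene_id = annot$gene_id[idx[1L]],
      chrom = annot$chrom[idx[1L]],
      strand = s,
      tss = if (s == "+") min(annot$start[idx]) else max(annot$end[idx]),
      exon_model_length_bp = sum(IRanges::width(merged)),
      n_exons = length(idx),
      start = min(annot$start[idx]),
      end = max(annot$end[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write an exon annotation as a BED-like TSV
#'
#' Inverse of [read_exon_annotation()] with `format = "bed"`.
#'
#' @param annot An [exon_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_annotation <- function(annot, path) {
  write_bed <- annot[, c("chrom", "start", "end", "exon_id", "gene_id",
                         "strand", "alt_types")]
  data.table::fwrite(write_bed, path, sep = "\t", quote = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}
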