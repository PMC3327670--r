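#' Read gene sets in GMT format
#'
#' One pathway per line: id, description, then tab-separated member gene
#' ids.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene ids.  The description
#'   fields are kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (any(lengths(sets) == 0L)) {
    stop("GMT contains an empty pathway", call. = FALSE)
  }
  attr(sets, "descriptions") <-
    setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric pathway enrichment of a gene list
#'
#' For every pathway, with `N` the size of the pathway universe (the union
#' of all pathway genes), `n` the pathway size, `M` the number of query
#' genes inside the universe and `k` the number of query genes in the
#' pathway, the one-sided enrichment p-value is the upper hypergeometric
#' tail `P(X >= k)`.  Query genes outside the universe are dropped before
#' computing `M`.  A record is significant when `p < alpha` *and* the
#' pathway holds at least `min_k` query genes.  P-values are raw (no
#' multiple-testing correction).
#'
#' @param query Character vector of query gene ids (e.g. the up-regulated
#'   DEGs of one contrast, or the genes owning at least one exon-variant
#'   call).
#' @param pathways Named list of pathway gene sets ([read_gmt()]).
#' @param alpha Significance level (default 0.05).
#' @param min_k Minimum number of query genes in the pathway (default 5).
#' @param category Optional label stored with every record (e.g.
#'   `"PAH_up"`).
#' @return Data frame with one row per pathway: `pathway_id, category, N,
#'   n, M, k, p, neg_log10_p, significant`, ordered by increasing `p`.
#' @export
enrich <- function(query, pathways, alpha = 0.05, min_k = 5,
                   category = NA_character_) {
  universe <- unique(unlist(pathways, use.names = FALSE))
  N <- length(universe)
  if (N == 0L) stop("empty pathway universe", call. = FALSE)
  query <- unique(intersect(query, universe))
  M <- length(query)
  out <- do.call(rbind, lapply(names(pathways), function(id) {
    genes <- intersect(pathways[[id]], universe)
    n <- length(genes)
    k <- length(intersect(query, genes))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
    data.frame(pathway_id = id, category = category, N = N, n = n, M = M,
               k = k, p = p, stringsAsFactors = FALSE)
  }))
  out$neg_log10_p <- -log10(out$p)
  out$significant <- out$p < alpha & out$k >= min_k
  out <- out[order(out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway-by-category heat matrix of enrichment strengths
#'
#' Builds the familiar pathway x category matrix of `-log10(p)` values,
#' with 0 in every non-significant cell.  Rows can be grouped/ordered by a
#' user-supplied pathway grouping (group labels are user annotation, not
#' computed).
#'
#' @param records Row-bound [enrich()] results across categories.
#' @param pathway_order Optional character vector fixing the row order
#'   (e.g. grouped pathways); defaults to all pathways present, sorted.
#' @return Numeric matrix (pathways x categories).
#' @export
heat_matrix <- function(records, pathway_order = NULL) {
  cats <- unique(records$category)
  paths <- if (is.null(pathway_order)) sort(unique(records$pathway_id)) else
    pathway_order
  m <- matrix(0, nrow = length(paths), ncol = length(cats),
              dimnames = list(paths, cats))
  sig <- records[records$significant & records$pathway_id %in% paths, ,
                 drop = FALSE]
  if (nrow(sig)) {
    m[cbind(match(sig$pathway_id, paths), match(sig$category, cats))] <-
      sig$neg_log10_p
  }
  m
}
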