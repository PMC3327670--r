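#' Exon expression filter for splicing analysis
#'
#' Exons whose mean RPKM stays below `threshold` in both compared
#' conditions are discarded before exon-usage testing, to reduce false
#' positives at low coverage.  One condition reaching the threshold
#' suffices.
#'
#' @param exon_rpkm Exon-level RPKM matrix (exons x samples).
#' @param samples Sample manifest (`sample_id`, `condition`).
#' @param contrast Named character vector `c(control = ..., treatment = ...)`.
#' @param threshold RPKM threshold (default 10).
#' @return Character vector of testable exon ids.
#' @export
exon_rpkm_filter <- function(exon_rpkm, samples, contrast, threshold = 10) {
  m_ctl <- rowMeans(exon_rpkm[, samples_for(samples, contrast[["control"]]),
                              drop = FALSE])
  m_trt <- rowMeans(exon_rpkm[, samples_for(samples, contrast[["treatment"]]),
                              drop = FALSE])
  rownames(exon_rpkm)[pmax(m_ctl, m_trt) >= threshold]
}

#' Exon-versus-rest-of-gene contingency tables
#'
#' For every exon the 2x2 table is built from replicate-pooled counts:
#' `a` exon reads in control, `b` exon reads in treatment, `c` and `d` the
#' reads of the *rest of the gene* in control and treatment.  Contrasting
#' the exon against the rest of its own gene removes gene-level
#' differential expression from the splicing signal, so that a significant
#' table reflects a change in exon *usage*.
#'
#' Exons that cannot be tested are dropped: single-exon genes (`c = d = 0`),
#' genes with zero reads in either condition (degenerate margin), and exons
#' with zero reads in both conditions.
#'
#' @param exon_counts Exon-level count matrix (exons x samples), covering
#'   *all* exons of each gene so the rest-of-gene counts are complete.
#' @param annot An [exon_annotation()] matching the rows of `exon_counts`.
#' @param control_samples,treatment_samples Column names of the two
#'   replicate groups.
#' @param exons Optional character vector restricting the output to these
#'   exon ids (e.g. the [exon_rpkm_filter()] survivors).
#' @return Data frame with columns `exon_id, gene_id, a, b, c, d`.
#' @export
build_contingency <- function(exon_counts, annot, control_samples,
                              treatment_samples, exons = NULL) {
  stopifnot(identical(rownames(exon_counts), annot$exon_id))
  ex_ctl <- rowSums(exon_counts[, control_samples, drop = FALSE])
  ex_trt <- rowSums(exon_counts[, treatment_samples, drop = FALSE])
  gene_ctl <- rowsum(ex_ctl, annot$gene_id)[, 1L]
  gene_trt <- rowsum(ex_trt, annot$gene_id)[, 1L]
  df <- data.frame(
    exon_id = annot$exon_id,
    gene_id = annot$gene_id,
    a = ex_ctl,
    b = ex_trt,
    c = gene_ctl[annot$gene_id] - ex_ctl,
    d = gene_trt[annot$gene_id] - ex_trt,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  if (any(df$c < 0) || any(df$d < 0)) {
    stop("exon counts exceed gene counts", call. = FALSE)
  }
  if (!is.null(exons)) df <- df[df$exon_id %in% exons, , drop = FALSE]
  testable <- !(df$c == 0 & df$d == 0) &          # single-exon gene
    (df$a + df$c) > 0 & (df$b + df$d) > 0 &       # gene expressed both sides
    (df$a + df$b) > 0                             # exon seen at all
  df <- df[testable, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact p-value by enumeration of all tables with the observed margins.
#' For `alternative = "two.sided"` the p-value sums the hypergeometric
#' probabilities of every table whose probability does not exceed that of
#' the observed table, ties compared with a relative tolerance of 1e-7.
#' `alternative = "greater"` is the upper tail on the top-left cell
#' (enrichment orientation).  A zero margin leaves a single admissible
#' table and `p = 1`.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (`rbind(c(a, b), c(c, d))`).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return The exact p-value.
#' @export
fisher_exact <- function(tab, alternative = "two.sided") {
  # kept lean: this is called once per exon per contrast, and exhaustively
  # in the enumeration checks
  if (length(tab) != 4L) stop("tab must be a 2x2 matrix", call. = FALSE)
  a <- tab[[1L]]; c <- tab[[2L]]; b <- tab[[3L]]; d <- tab[[4L]]
  if (a < 0 || b < 0 || c < 0 || d < 0 || a %% 1 != 0 || b %% 1 != 0 ||
      c %% 1 != 0 || d %% 1 != 0) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  r1 <- a + b; c1 <- a + c; c2 <- b + d
  lo <- if (r1 > c2) r1 - c2 else 0
  hi <- if (r1 < c1) r1 else c1
  x <- lo:hi
  probs <- stats::dhyper(x, c1, c2, r1)
  p <- if (alternative[[1L]] == "greater") {
    sum(probs[x >= a])
  } else {
    sum(probs[probs <= probs[[a - lo + 1L]] * (1 + 1e-7)])
  }
  if (p > 1) 1 else p
}

#' Posterior sign-error rate for an exon-usage difference
#'
#' The exon proportion of the gene's reads is modelled independently in the
#' two conditions as Beta-Binomial with a common Beta prior:
#' `theta_ctrl ~ Beta(a + p1, c + p2)` and `theta_trt ~ Beta(b + p1, d + p2)`
#' for `prior = c(p1, p2)` (uniform by default).  The error rate is the
#' posterior probability that the apparent direction of the difference is
#' wrong,
#' `e = min(P(theta_trt > theta_ctrl), P(theta_trt < theta_ctrl))`.
#'
#' The default method evaluates both orderings by adaptive quadrature of
#' `P(theta_trt <> x)` against the control posterior density, restricted to
#' the numerically supported quantile range so that sharply concentrated
#' posteriors (deep pooled counts) are handled accurately; each tail is
#' integrated directly, which keeps tiny error rates (< 1e-10) free of
#' cancellation.  `method = "mc"` instead draws from the two posteriors.
#'
#' @param tab 2x2 matrix `rbind(c(a, b), c(c, d))` (exon / rest-of-gene by
#'   control / treatment).
#' @param prior Beta prior parameters (default `c(1, 1)`, uniform).
#' @param method `"quadrature"` (default, deterministic) or `"mc"`.
#' @param mc_draws Number of Monte-Carlo draws (default 1e6).
#' @param seed Seed for the Monte-Carlo method (ignored for quadrature).
#' @return The sign-error rate `e` in `[0, 0.5]`.
#' @export
bayes_error_rate <- function(tab, prior = c(1, 1),
                             method = c("quadrature", "mc"),
                             mc_draws = 1e6, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  a_ctl <- tab[1L, 1L] + prior[1L]; b_ctl <- tab[2L, 1L] + prior[2L]
  a_trt <- tab[1L, 2L] + prior[1L]; b_trt <- tab[2L, 2L] + prior[2L]
  if (method == "mc") {
    return(with_seed(seed, {
      th_c <- stats::rbeta(mc_draws, a_ctl, b_ctl)
      th_t <- stats::rbeta(mc_draws, a_trt, b_trt)
      min(mean(th_t > th_c), mean(th_t < th_c))
    }))
  }
  # integrate over the control posterior, inside its supported range
  lo <- stats::qbeta(1e-14, a_ctl, b_ctl)
  hi <- stats::qbeta(1e-14, a_ctl, b_ctl, lower.tail = FALSE)
  tail_p <- function(lower_tail) {
    f <- function(x) stats::dbeta(x, a_ctl, b_ctl) *
      stats::pbeta(x, a_trt, b_trt, lower.tail = lower_tail)
    stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-14,
                     subdivisions = 500L)$value
  }
  p_lt <- tail_p(TRUE)    # P(theta_trt < theta_ctrl)
  p_gt <- tail_p(FALSE)   # P(theta_trt > theta_ctrl)
  max(0, min(p_lt, p_gt))
}

#' Test exon usage for every contingency table
#'
#' Adds the two-sided Fisher p-value, the Bayesian sign-error rate and the
#' usage direction to a [build_contingency()] table.  Direction is
#' `inclusion` when the pooled exon proportion is higher in the treatment
#' condition (TAC / exercise) than in the control (sham / sedentary), and
#' `exclusion` otherwise.
#'
#' @param contingency Data frame from [build_contingency()].
#' @param bayes_method,mc_draws,seed Passed to [bayes_error_rate()].
#' @return The input with columns `fisher_p, bayes_e, direction` appended.
#' @export
test_exon_usage <- function(contingency, bayes_method = "quadrature",
                            mc_draws = 1e6, seed = NULL) {
  n <- nrow(contingency)
  fisher_p <- numeric(n)
  bayes_e <- numeric(n)
  direction <- character(n)
  for (i in seq_len(n)) {
    tab <- rbind(c(contingency$a[i], contingency$b[i]),
                 c(contingency$c[i], contingency$d[i]))
    fisher_p[i] <- fisher_exact(tab)
    bayes_e[i] <- bayes_error_rate(tab, method = bayes_method,
                                   mc_draws = mc_draws, seed = seed)
    incl <- contingency$b[i] * (contingency$a[i] + contingency$c[i]) >
      contingency$a[i] * (contingency$b[i] + contingency$d[i])
    direction[i] <- if (incl) "inclusion" else "exclusion"
  }
  contingency$fisher_p <- fisher_p
  contingency$bayes_e <- bayes_e
  contingency$direction <- direction
  contingency
}

#' Call exon inclusion/exclusion variants
#'
#' Applies the significance cascade to tested exons: two-sided Fisher
#' `p < alpha`, Bayesian sign-error `e <= e_max`, and a non-empty known
#' alternative-splicing label (the knownAlt restriction).  Exons without a
#' label are never reported, whatever their significance.
#'
#' @param tests Data frame from [test_exon_usage()].
#' @param annot An [exon_annotation()] supplying `alt_types`.
#' @param alpha Fisher significance level (default 0.05).
#' @param e_max Maximum sign-error rate (default 0.1).
#' @param contrast Contrast label stored with the calls (e.g. `"PAH"`).
#' @return Data frame of calls: `exon_id, gene_id, fisher_p, bayes_e,
#'   direction, alt_types, contrast`.
#' @export
call_exon_variants <- function(tests, annot, alpha = 0.05, e_max = 0.1,
                               contrast = NA_character_) {
  alt <- setNames(annot$alt_types, annot$exon_id)
  keep <- tests$fisher_p < alpha & tests$bayes_e <= e_max &
    nzchar(alt[tests$exon_id])
  out <- tests[keep, c("exon_id", "gene_id", "fisher_p", "bayes_e",
                       "direction"), drop = FALSE]
  out$alt_types <- unname(alt[out$exon_id])
  out$contrast <- rep_len(contrast, nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarise exon-variant calls by direction and splicing type
#'
#' @param calls Data frame of [call_exon_variants()] results (one or both
#'   contrasts row-bound).
#' @return List with `directions` (per contrast: inclusion and exclusion
#'   counts) and `types` (per contrast: weight and proportion of each
#'   alternative-splicing type; an exon carrying k labels contributes 1/k
#'   to each).
#' @export
summarize_variant_types <- function(calls) {
  if (nrow(calls) == 0L) {
    return(list(
      directions = data.frame(contrast = character(), inclusion = integer(),
                              exclusion = integer()),
      types = data.frame(contrast = character(), alt_type = character(),
                         weight = numeric(), proportion = numeric())))
  }
  directions <- do.call(rbind, lapply(split(calls, calls$contrast),
    function(cc) data.frame(
      contrast = cc$contrast[1L],
      inclusion = sum(cc$direction == "inclusion"),
      exclusion = sum(cc$direction == "exclusion"),
      stringsAsFactors = FALSE)))
  types_long <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    tt <- strsplit(calls$alt_types[i], ",", fixed = TRUE)[[1L]]
    tt <- tt[nzchar(tt)]
    data.frame(contrast = calls$contrast[i], alt_type = tt,
               weight = 1 / length(tt), stringsAsFactors = FALSE)
  }))
  types <- do.call(rbind, lapply(split(types_long, types_long$contrast),
    function(cc) {
      w <- tapply(cc$weight, cc$alt_type, sum)
      data.frame(contrast = cc$contrast[1L], alt_type = names(w),
                 weight = as.numeric(w),
                 proportion = as.numeric(w) / sum(w),
                 stringsAsFactors = FALSE)
    }))
  rownames(directions) <- rownames(types) <- NULL
  list(directions = directions, types = types)
}
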