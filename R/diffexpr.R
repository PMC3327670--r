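#' Two-sample Student's t-test
#'
#' Equal-variance (pooled) two-sided Student's t-test with
#' `df = n1 + n2 - 2`, the test applied to per-gene RPKM values across
#' biological replicates.  Degenerate inputs are resolved explicitly: if the
#' pooled variance is zero and the means are equal, `t = 0, p = 1`; if the
#' pooled variance is zero and the means differ, `t = +/-Inf, p = 0`.
#'
#' @param xs,ys Numeric replicate vectors (each of length >= 2).
#' @param var_equal Pooled variance (default `TRUE`); `FALSE` gives the
#'   Welch test.
#' @return Named numeric vector `c(t, p, df)`, with
#'   `t = (mean(xs) - mean(ys)) / se`.
#' @export
student_t <- function(xs, ys, var_equal = TRUE) {
  n1 <- length(xs); n2 <- length(ys)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  m1 <- mean(xs); m2 <- mean(ys)
  v1 <- stats::var(xs); v2 <- stats::var(ys)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se == 0) n1 + n2 - 2 else
      (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (m1 == m2) return(c(t = 0, p = 1, df = df))
    return(c(t = sign(m1 - m2) * Inf, p = 0, df = df))
  }
  t <- (m1 - m2) / se
  c(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Fold change and log-1.5 fold change
#'
#' `fc = (mean_treatment + c) / (mean_control + c)` with pseudocount `c`
#' guarding against zero denominators (turned-on genes have near-zero
#' control means), and `log15_fc = log(fc) / log(1.5)`, the scale on which
#' the differential-expression threshold `|log15_fc| >= 1` means "at least
#' 1.5-fold".
#'
#' @param mean_treatment,mean_control Non-negative group means.
#' @param pseudocount Added to both means (default 0.25 RPKM).
#' @return Named numeric vector `c(fc, log15_fc)`.
#' @export
fold_change <- function(mean_treatment, mean_control, pseudocount = 0.25) {
  if (any(mean_treatment < 0) || any(mean_control < 0)) {
    stop("group means must be non-negative", call. = FALSE)
  }
  fc <- (mean_treatment + pseudocount) / (mean_control + pseudocount)
  c(fc = fc, log15_fc = log(fc) / log(1.5))
}

#' Call differentially expressed genes between two conditions
#'
#' A gene is *tested* only when the larger of the two group mean RPKM values
#' reaches `floor`.  A tested gene is called `up` when `p < alpha` and
#' `log15_fc >= min_abs_log15fc`, `down` when `p < alpha` and
#' `log15_fc <= -min_abs_log15fc`, and `ns` otherwise.  P-values are raw by
#' default; `bh = TRUE` switches the call to Benjamini-Hochberg adjusted
#' p-values (also reported in `p_adj`).
#'
#' @param rpkm Gene-level RPKM matrix (genes x samples).
#' @param control_samples,treatment_samples Disjoint character vectors of
#'   column names.
#' @param alpha Significance level (default 0.05).
#' @param min_abs_log15fc Fold-change threshold on the log-1.5 scale
#'   (default 1, i.e. 1.5-fold).
#' @param floor Expression floor in RPKM (default 2).
#' @param pseudocount Fold-change pseudocount (default 0.25).
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @param bh Use Benjamini-Hochberg adjusted p-values for the call?
#'   Default `FALSE`.
#' @return A `deg_table` data frame with one row per gene: `gene_id,
#'   mean_control, mean_treatment, fold_change, log15_fc, t_statistic,
#'   p_value, p_adj, tested, call, turned_on, opposite`.
#' @export
call_degs <- function(rpkm, control_samples, treatment_samples,
                      alpha = 0.05, min_abs_log15fc = 1, floor = 2,
                      pseudocount = 0.25, var_equal = TRUE, bh = FALSE) {
  if (length(intersect(control_samples, treatment_samples))) {
    stop("control and treatment sample sets overlap", call. = FALSE)
  }
  ctl <- rpkm[, control_samples, drop = FALSE]
  trt <- rpkm[, treatment_samples, drop = FALSE]
  mean_control <- rowMeans(ctl)
  mean_treatment <- rowMeans(trt)
  tested <- pmax(mean_control, mean_treatment) >= floor
  fc <- (mean_treatment + pseudocount) / (mean_control + pseudocount)
  log15 <- log(fc) / log(1.5)
  t_stat <- rep(NA_real_, nrow(rpkm))
  p <- rep(NA_real_, nrow(rpkm))
  for (i in which(tested)) {
    tp <- student_t(trt[i, ], ctl[i, ], var_equal = var_equal)
    t_stat[i] <- tp[["t"]]
    p[i] <- tp[["p"]]
  }
  p_adj <- rep(NA_real_, nrow(rpkm))
  p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  p_eff <- if (bh) p_adj else p
  call <- rep("ns", nrow(rpkm))
  call[tested & p_eff < alpha & log15 >= min_abs_log15fc] <- "up"
  call[tested & p_eff < alpha & log15 <= -min_abs_log15fc] <- "down"
  out <- data.frame(
    gene_id = rownames(rpkm),
    mean_control = mean_control,
    mean_treatment = mean_treatment,
    fold_change = fc,
    log15_fc = log15,
    t_statistic = t_stat,
    p_value = p,
    p_adj = p_adj,
    tested = tested,
    call = call,
    turned_on = FALSE,
    opposite = FALSE,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Classify turned-on genes
#'
#' Turned-on genes are barely detectable in the normal (sham) and
#' exercise-trained heart but activated under pressure overload: called
#' `up` in the sham-vs-TAC contrast, with mean sham RPKM and mean exercise
#' RPKM (when exercise samples are present) below `floor`, and mean TAC
#' RPKM at or above `floor`.
#'
#' @param degs `deg_table` from the sham-vs-TAC contrast.
#' @param rpkm Gene-level RPKM matrix.
#' @param samples Sample manifest (`sample_id`, `condition`).
#' @param floor Expression floor (default 2 RPKM).
#' @return Character vector of turned-on gene ids.
#' @export
classify_turned_on <- function(degs, rpkm, samples, floor = 2) {
  cond_mean <- function(cond) {
    cols <- samples_for(samples, cond)
    if (!length(cols)) return(NULL)
    rowMeans(rpkm[, cols, drop = FALSE])
  }
  sham <- cond_mean("sham")
  tac <- cond_mean("TAC")
  if (is.null(sham) || is.null(tac)) {
    stop("samples must include sham and TAC conditions", call. = FALSE)
  }
  exercise <- cond_mean("exercise")
  up <- degs$gene_id[degs$call == "up"]
  ok <- sham[up] < floor & tac[up] >= floor
  if (!is.null(exercise)) ok <- ok & exercise[up] < floor
  up[ok]
}

#' Classify oppositely regulated genes
#'
#' Genes called in both contrasts (pathological and physiological
#' hypertrophy) with opposite signs: `up` in one and `down` in the other.
#' The function is symmetric in its two arguments.
#'
#' @param degs_pah,degs_phh `deg_table`s for the two contrasts, computed on
#'   the same gene universe.
#' @return Character vector of oppositely regulated gene ids.
#' @export
classify_opposite <- function(degs_pah, degs_phh) {
  a <- setNames(degs_pah$call, degs_pah$gene_id)
  b <- setNames(degs_phh$call, degs_phh$gene_id)
  common <- intersect(names(a), names(b))
  common[(a[common] == "up" & b[common] == "down") |
           (a[common] == "down" & b[common] == "up")]
}

#' Set category flags on a DEG table
#'
#' @param degs A `deg_table`.
#' @param turned_on,opposite Character vectors of gene ids.
#' @return The table with `turned_on` / `opposite` flags set.
#' @export
flag_deg_categories <- function(degs, turned_on = character(),
                                opposite = character()) {
  degs$turned_on <- degs$gene_id %in% turned_on
  degs$opposite <- degs$gene_id %in% opposite
  degs
}
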