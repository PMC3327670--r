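#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so that seeded helpers do not disturb the caller's
#' random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG alone.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic TSV writers used by every stage so reruns are byte-identical
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, scipen = 50L,
                     eol = "\n", na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  data.table::setDF(data.table::fread(path, sep = "\t", header = TRUE,
                                      na.strings = "NA", ...))
}

# condition vocabulary of the two-contrast hypertrophy design
#' Standard two-contrast design of the pipeline
#'
#' The pipeline compares sham vs. TAC ("PAH", pathological hypertrophy) and
#' sedentary vs. exercise ("PHH", physiological hypertrophy).
#'
#' @return Named list with one element per contrast, each a named character
#'   vector with elements `control` and `treatment`.
#' @export
default_contrasts <- function() {
  list(PAH = c(control = "sham", treatment = "TAC"),
       PHH = c(control = "sedentary", treatment = "exercise"))
}

conditions_vocab <- function() c("sham", "TAC", "sedentary", "exercise")

#' Known alternative-splicing type vocabulary
#'
#' The eight feature labels of the UCSC knownAlt track used to classify
#' exon variants.
#'
#' @return Character vector of the eight labels.
#' @export
known_alt_types <- function() {
  c("altPromoter", "cassetteExon", "altFinish", "altThreePrime",
    "altFivePrime", "bleedingExon", "retainedIntron", "strangeSplice")
}

samples_for <- function(samples, condition) {
  samples$sample_id[samples$condition == condition]
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}
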