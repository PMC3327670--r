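#' Pipeline configuration
#'
#' Collects the input paths, thresholds and flags of a full run.  The
#' threshold defaults are the analysis criteria used throughout:
#' 2 RPKM expression floor, 10 RPKM exon filter, `p < 0.05`,
#' `|log1.5 FC| >= 1`, sign-error `e <= 0.1`, and at least 5 query genes
#' per enriched pathway.
#'
#' @param annotation Path to the exon annotation BED.
#' @param reads_manifest Path to the sample manifest TSV.
#' @param genome Optional genome FASTA (needed for the motif stage).
#' @param gmt Optional pathway GMT (needed for the enrichment stage).
#' @param motifs Consensus motifs scanned by the motif stage (default the
#'   MAZ-binding pair `GGGAGGG` / `CCCTCCC`).
#' @param rpkm_floor,exon_rpkm_min,alpha,min_abs_log15fc,bayes_e_max,min_pathway_k
#'   Thresholds (defaults above).
#' @param fc_pseudocount Fold-change pseudocount (default 0.25).
#' @param drop_chrM Drop mitochondrial reads (default `TRUE`).
#' @param chrM_name Mitochondrial chromosome name (default `"chrM"`).
#' @param bh_correction Use BH-adjusted p-values for DEG calls (default
#'   `FALSE`, raw p-values).
#' @param expressed_mode Expressed-gene rule, `"any_replicate"` or
#'   `"group_mean"`.
#' @param seed Seed recorded and used for any stochastic option.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, reads_manifest, genome = NULL,
                            gmt = NULL, motifs = c("GGGAGGG", "CCCTCCC"),
                            rpkm_floor = 2, exon_rpkm_min = 10,
                            alpha = 0.05, min_abs_log15fc = 1,
                            bayes_e_max = 0.1, min_pathway_k = 5,
                            fc_pseudocount = 0.25,
                            drop_chrM = TRUE, chrM_name = "chrM",
                            bh_correction = FALSE,
                            expressed_mode = "any_replicate", seed = 1L) {
  stopifnot(rpkm_floor >= 0, exon_rpkm_min >= 0, alpha >= 0,
            min_abs_log15fc >= 0, bayes_e_max >= 0, min_pathway_k >= 0)
  structure(list(
    annotation = annotation, reads_manifest = reads_manifest,
    genome = genome, gmt = gmt, motifs = motifs,
    rpkm_floor = rpkm_floor, exon_rpkm_min = exon_rpkm_min, alpha = alpha,
    min_abs_log15fc = min_abs_log15fc, bayes_e_max = bayes_e_max,
    min_pathway_k = min_pathway_k, fc_pseudocount = fc_pseudocount,
    drop_chrM = drop_chrM, chrM_name = chrM_name,
    bh_correction = bh_correction, expressed_mode = expressed_mode,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Relative paths are resolved against the JSON file's directory.
#'
#' @param path Path to a JSON config (e.g. the `fixture.json` written by
#'   [emit_fixture()]).
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- modifyList(vals, list(...))
  cfg <- do.call(pipeline_config, vals)
  for (f in c("annotation", "reads_manifest", "genome", "gmt")) {
    if (!is.null(cfg[[f]]) && !grepl("^/", cfg[[f]])) {
      cfg[[f]] <- file.path(dirname(path), cfg[[f]])
    }
  }
  cfg
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — alignment filtering, exon and
#' gene counting, RPKM, differential expression and gene-set
#' classification for both contrasts, exon-variant calling, pathway
#' enrichment of the six DEG/AS categories, and (when a genome is
#' configured) consensus-motif enrichment — and writes every stage's TSV
#' outputs plus a JSON run manifest into `out_dir`.  Outputs are pure
#' functions of the inputs and the configuration: rerunning with the same
#' config reproduces them byte for byte.
#'
#' The six enrichment categories are the up- and down-regulated DEGs and
#' the exon-variant genes of each contrast (`PAH_up, PAH_down, PAH_AS,
#' PHH_up, PHH_down, PHH_AS`).  The motif stage takes the oppositely
#' regulated genes as foreground (the classic promoter-analysis target of
#' this design) against all other tested genes; it is skipped when no
#' genome FASTA is configured or the foreground is empty.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list of class `dualseq_run` with the in-memory results:
#'   `counts`, `rpkm_gene`, `rpkm_exon`, `expressed`, `degs` (per
#'   contrast), `turned_on`, `opposite`, `exon_tests`, `variant_calls`,
#'   `variant_summary`, `enrichment`, `heat`, `motif`, `manifest`.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[dualseq] ", fmt), ...))
  }

  # --- load inputs -------------------------------------------------------
  annot <- read_exon_annotation(config$annotation)
  samples <- read_sample_manifest(config$reads_manifest)
  reads <- lapply(samples$path, read_reads_bed)
  names(reads) <- samples$sample_id
  models <- gene_models(annot)

  # --- quantify ----------------------------------------------------------
  log_stage("quantify: %d samples, %d exons, %d genes", length(reads),
            nrow(annot), nrow(models))
  counts <- count_matrices(reads, annot, filter = TRUE,
                           drop_chrM = config$drop_chrM,
                           chrM_name = config$chrM_name)
  samples$mapped_reads_total <- counts$mapped_reads_total[samples$sample_id]
  exon_len <- setNames(annot$end - annot$start, annot$exon_id)
  gene_len <- setNames(models$exon_model_length_bp, models$gene_id)
  rpkm_exon <- compute_rpkm(counts$exon, exon_len, counts$mapped_reads_total)
  rpkm_gene <- compute_rpkm(counts$gene, gene_len, counts$mapped_reads_total)
  expressed <- expressed_genes(rpkm_gene, samples, floor = config$rpkm_floor,
                               mode = config$expressed_mode)
  write_matrix <- function(m, path) write_matrix_tsv(m, path)
  write_matrix(counts$exon, file.path(out_dir, "counts_exon.tsv"))
  write_matrix(counts$gene, file.path(out_dir, "counts_gene.tsv"))
  write_matrix(rpkm_exon, file.path(out_dir, "rpkm_exon.tsv"))
  write_matrix(rpkm_gene, file.path(out_dir, "rpkm_gene.tsv"))
  write_tsv(samples[, c("sample_id", "condition", "replicate",
                        "mapped_reads_total")],
            file.path(out_dir, "samples_mapped.tsv"))

  # --- differential expression ------------------------------------------
  contrasts <- default_contrasts()
  degs <- list()
  for (cn in names(contrasts)) {
    ctl <- samples_for(samples, contrasts[[cn]][["control"]])
    trt <- samples_for(samples, contrasts[[cn]][["treatment"]])
    degs[[cn]] <- call_degs(rpkm_gene, ctl, trt, alpha = config$alpha,
                            min_abs_log15fc = config$min_abs_log15fc,
                            floor = config$rpkm_floor,
                            pseudocount = config$fc_pseudocount,
                            bh = config$bh_correction)
  }
  turned_on <- classify_turned_on(degs$PAH, rpkm_gene, samples,
                                  floor = config$rpkm_floor)
  opposite <- classify_opposite(degs$PAH, degs$PHH)
  degs <- lapply(degs, flag_deg_categories, turned_on = turned_on,
                 opposite = opposite)
  for (cn in names(degs)) {
    write_tsv(degs[[cn]], file.path(out_dir, sprintf("degs_%s.tsv", cn)))
  }
  writeLines(turned_on, file.path(out_dir, "turned_on_genes.txt"))
  writeLines(opposite, file.path(out_dir, "opposite_genes.txt"))
  log_stage("diffexpr: %d/%d DEGs (PAH/PHH), %d turned-on, %d opposite",
            sum(degs$PAH$call != "ns"), sum(degs$PHH$call != "ns"),
            length(turned_on), length(opposite))

  # --- splicing ----------------------------------------------------------
  exon_tests <- list(); calls <- list()
  for (cn in names(contrasts)) {
    ctl <- samples_for(samples, contrasts[[cn]][["control"]])
    trt <- samples_for(samples, contrasts[[cn]][["treatment"]])
    testable <- exon_rpkm_filter(rpkm_exon, samples, contrasts[[cn]],
                                 threshold = config$exon_rpkm_min)
    ct <- build_contingency(counts$exon, annot, ctl, trt, exons = testable)
    exon_tests[[cn]] <- test_exon_usage(ct)
    calls[[cn]] <- call_exon_variants(exon_tests[[cn]], annot,
                                      alpha = config$alpha,
                                      e_max = config$bayes_e_max,
                                      contrast = cn)
    write_tsv(exon_tests[[cn]],
              file.path(out_dir, sprintf("exon_tests_%s.tsv", cn)))
  }
  variant_calls <- rbind(calls$PAH, calls$PHH)
  variant_summary <- summarize_variant_types(variant_calls)
  write_tsv(variant_calls, file.path(out_dir, "exon_variants.tsv"))
  write_tsv(variant_summary$directions,
            file.path(out_dir, "variant_directions.tsv"))
  write_tsv(variant_summary$types, file.path(out_dir, "variant_types.tsv"))
  log_stage("splicing: %d calls (%d PAH, %d PHH)", nrow(variant_calls),
            nrow(calls$PAH), nrow(calls$PHH))

  # --- enrichment --------------------------------------------------------
  enrichment <- NULL; heat <- NULL
  if (!is.null(config$gmt)) {
    pathways <- read_gmt(config$gmt)
    queries <- list(
      PAH_up = degs$PAH$gene_id[degs$PAH$call == "up"],
      PAH_down = degs$PAH$gene_id[degs$PAH$call == "down"],
      PAH_AS = unique(calls$PAH$gene_id),
      PHH_up = degs$PHH$gene_id[degs$PHH$call == "up"],
      PHH_down = degs$PHH$gene_id[degs$PHH$call == "down"],
      PHH_AS = unique(calls$PHH$gene_id)
    )
    enrichment <- do.call(rbind, lapply(names(queries), function(cat) {
      enrich(queries[[cat]], pathways, alpha = config$alpha,
             min_k = config$min_pathway_k, category = cat)
    }))
    heat <- heat_matrix(enrichment)
    write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
    write_matrix(heat, file.path(out_dir, "enrichment_heat.tsv"))
    log_stage("enrichment: %d significant pathway/category records",
              sum(enrichment$significant))
  }

  # --- motif -------------------------------------------------------------
  motif <- NULL
  if (!is.null(config$genome) && length(opposite)) {
    ups <- extract_upstream(models, config$genome)
    background <- setdiff(
      degs$PAH$gene_id[degs$PAH$tested | degs$PHH$tested], opposite)
    background <- intersect(background, names(ups))
    fg <- intersect(opposite, names(ups))
    if (length(fg) && length(background)) {
      motif <- do.call(rbind, lapply(config$motifs, function(m) {
        motif_enrichment(fg, background, ups, m)
      }))
      write_tsv(motif, file.path(out_dir, "motif_enrichment.tsv"))
      log_stage("motif: %d motifs scanned on %d fg / %d bg genes",
                length(config$motifs), length(fg), length(background))
    }
  }

  # --- manifest ----------------------------------------------------------
  manifest <- list(
    package = "dualseq",
    version = as.character(packageVersion("dualseq")),
    seed = config$seed,
    config = unclass(config),
    records = list(
      samples = nrow(samples),
      exons = nrow(annot),
      genes = nrow(models),
      degs_pah = sum(degs$PAH$call != "ns"),
      degs_phh = sum(degs$PHH$call != "ns"),
      turned_on = length(turned_on),
      opposite = length(opposite),
      exon_variants = nrow(variant_calls),
      enriched = if (is.null(enrichment)) 0L else
        sum(enrichment$significant)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(
    counts = counts, rpkm_gene = rpkm_gene, rpkm_exon = rpkm_exon,
    samples = samples, expressed = expressed, degs = degs,
    turned_on = turned_on, opposite = opposite, exon_tests = exon_tests,
    variant_calls = variant_calls, variant_summary = variant_summary,
    enrichment = enrichment, heat = heat, motif = motif,
    manifest = manifest, out_dir = out_dir
  ), class = "dualseq_run")
}

#' @export
print.dualseq_run <- function(x, ...) {
  r <- x$manifest$records
  cat("dualseq run —", r$samples, "samples,", r$genes, "genes,",
      r$exons, "exons\n")
  cat("  DEGs: PAH", r$degs_pah, "/ PHH", r$degs_phh,
      "| turned-on", r$turned_on, "| opposite", r$opposite, "\n")
  cat("  exon variants:", r$exon_variants,
      "| significant pathway records:", r$enriched, "\n")
  cat("  outputs:", x$out_dir, "\n")
  invisible(x)
}
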