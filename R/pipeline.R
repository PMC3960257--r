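# Pipeline configuration and staged orchestration.

pipeline_defaults <- function() {
  list(
    fasta = NULL, gff3 = NULL, rna_fastq = NULL, srna_fastq = NULL,
    out_dir = ".", stages = c("structure", "codon_usage", "repeats",
                              "expression", "editing", "srna"),
    seed = 1L,
    min_ir_length = 1000, repeat_min_length = 20, repeat_max_e = 1e-3,
    max_mismatch = 2, multimap_policy = "all",
    editing_min_coverage = 5, editing_min_alt_fraction = 0.1,
    srna_min_reads = 20, srna_enrichment_ratio = 5, srna_merge_gap = 10
  )
}

#' Build (or load) a validated pipeline configuration
#'
#' Unknown keys are rejected; every threshold has its documented default.
#'
#' @param ... Named configuration values overriding the defaults, or a
#'   single `path` argument naming a YAML file of them.
#' @param path Optional YAML file of configuration values.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., path = NULL) {
  cfg <- pipeline_defaults()
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals <- utils::modifyList(vals, list(...))
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown)) {
    px_abort(paste("unknown configuration keys:", paste(unknown, collapse = ", ")),
             "bad_config")
  }
  for (k in c("min_ir_length", "repeat_min_length", "max_mismatch",
              "editing_min_coverage", "srna_min_reads", "srna_merge_gap", "seed")) {
    if (k %in% names(vals) && !is.numeric(vals[[k]])) {
      px_abort(sprintf("configuration key %s must be numeric", k), "bad_config")
    }
  }
  cfg <- utils::modifyList(cfg, vals)
  bad_stage <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad_stage)) {
    px_abort(paste("unknown stages:", paste(bad_stage, collapse = ", ")), "bad_config")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order — structure detection, codon
#' usage, repeat survey, expression profiling, editing calling, small-RNA
#' footprints — writing one stamped TSV per stage into `out_dir` and
#' returning the result tables. Stages whose inputs are missing from the
#' configuration raise an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Named list of result tibbles, one per executed stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$fasta)) px_abort("pipeline requires a fasta input", "bad_config")
  genome <- read_fasta(config$fasta)
  annotation <- if (!is.null(config$gff3)) read_gff3(config$gff3) else NULL
  results <- list()
  partition <- NULL
  alignments <- NULL
  rna_reads <- NULL

  need <- function(x, what, stage) {
    if (is.null(x)) px_abort(sprintf("stage %s requires %s", stage, what), "missing_input")
    x
  }
  out <- function(name) file.path(config$out_dir, paste0(name, ".tsv"))

  for (stage in config$stages) {
    if (stage == "structure") {
      partition <- detect_quadripartite(genome, config$min_ir_length)
      tbl <- tidy(partition)
      tbl$gc <- vapply(tbl$region, function(r) {
        gc_content(plastome(region_sequence(genome, partition, r), circular = FALSE))
      }, numeric(1))
      write_report_tsv(tbl, out("structure"), "structure",
                       list(min_ir_length = config$min_ir_length))
      results$structure <- tbl
    } else if (stage == "codon_usage") {
      need(annotation, "a gff3 annotation", stage)
      usage <- codon_usage(annotation, genome)
      write_report_tsv(tibble::as_tibble(usage), out("codon_usage"), "codon_usage")
      results$codon_usage <- usage
    } else if (stage == "repeats") {
      if (is.null(partition)) {
        partition <- tryCatch(detect_quadripartite(genome, config$min_ir_length),
                              error = function(e) NULL)
      }
      hits <- find_maximal_repeats(genome, config$repeat_min_length,
                                   config$repeat_max_e, annotation = annotation,
                                   partition = partition)
      write_report_tsv(hits, out("repeats"), "repeats",
                       list(min_length = config$repeat_min_length,
                            max_e = config$repeat_max_e))
      results$repeats <- hits
    } else if (stage == "expression") {
      need(annotation, "a gff3 annotation", stage)
      rna_reads <- rna_reads %||% read_fastq(need(config$rna_fastq, "rna_fastq", stage))
      alignments <- alignments %||% map_reads(rna_reads, genome, config$max_mismatch)
      prof <- expression_profile(alignments, annotation, config$multimap_policy)
      write_report_tsv(tibble::as_tibble(prof), out("expression"), "expression",
                       list(max_mismatch = config$max_mismatch,
                            multimap_policy = config$multimap_policy))
      results$expression <- prof
    } else if (stage == "editing") {
      need(annotation, "a gff3 annotation", stage)
      rna_reads <- rna_reads %||% read_fastq(need(config$rna_fastq, "rna_fastq", stage))
      alignments <- alignments %||% map_reads(rna_reads, genome, config$max_mismatch)
      pile <- build_pileup(alignments, rna_reads, genome)
      sites <- call_editing_sites(pile, genome, annotation,
                                  config$editing_min_coverage,
                                  config$editing_min_alt_fraction)
      write_report_tsv(sites, out("editing"), "editing",
                       list(min_coverage = config$editing_min_coverage,
                            min_alt_fraction = config$editing_min_alt_fraction))
      results$editing <- sites
    } else if (stage == "srna") {
      srna_reads <- read_fastq(need(config$srna_fastq, "srna_fastq", stage))
      loci <- srna_profile(srna_reads, genome, annotation,
                           min_reads = config$srna_min_reads,
                           enrichment_ratio = config$srna_enrichment_ratio,
                           merge_gap = config$srna_merge_gap)
      write_report_tsv(loci, out("srna"), "srna",
                       list(min_reads = config$srna_min_reads,
                            enrichment_ratio = config$srna_enrichment_ratio,
                            merge_gap = config$srna_merge_gap))
      results$srna <- loci
    }
  }
  results
}
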