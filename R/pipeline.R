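# Pipeline entry points tying the stages together: classify a cohort from
# files on disk, design reporter constructs for one gene, and simulate a
# synthetic cohort. A thin command-line wrapper over these functions ships
# in inst/cli/txiso.R.

#' A compact default reporter payload
#'
#' The first ten codons of a GFP-style coding sequence: a multiple of three
#' bases with no frame-0 stop, sufficient for frame bookkeeping. Any real
#' reporter CDS satisfying [edit_op()]'s payload rules can be used instead.
#' @return A nucleotide string.
#' @export
default_reporter_payload <- function() "ATGGTGAGCAAGGGCGAGGAGCTGTTCACC"

#' Pipeline run configuration
#'
#' @param annotation GFF3 path.
#' @param genome FASTA path.
#' @param evidence Evidence TSV path (optional).
#' @param out_dir Output directory.
#' @param strong_threshold,tolerance,nmd_distance Classification parameters
#'   (see [classify_config()]).
#' @param arm_length Homology-arm length for construct design.
#' @param seed Integer seed for any randomized step.
#' @return A named list.
#' @export
run_config <- function(annotation, genome, evidence = NULL, out_dir = ".",
                       strong_threshold = 2L, tolerance = 0L,
                       nmd_distance = 50L, arm_length = 50L, seed = 1L) {
  stopifnot(strong_threshold > 0L, nmd_distance > 0L, arm_length > 0L)
  list(annotation = annotation, genome = genome, evidence = evidence,
       out_dir = out_dir,
       config = classify_config(strong_threshold, tolerance, nmd_distance),
       arm_length = as.integer(arm_length), seed = as.integer(seed))
}

#' Classify every gene of an annotated cohort
#'
#' Reads the annotation, genome and evidence named in the configuration,
#' classifies each gene and writes `classifications.tsv` (one row per gene)
#' and `summary.tsv` (category counts; the counts partition the cohort) to
#' the output directory.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `results` and `summary` data.frames.
#' @export
run_classify <- function(cfg) {
  genome <- read_genome(cfg$genome)
  genes <- parse_gene_models(cfg$annotation, genome)
  records <- if (!is.null(cfg$evidence)) read_evidence(cfg$evidence) else NULL
  message(length(genes), " gene(s) parsed")
  results <- classify_cohort(genes, genome, records, cfg$config)
  summary <- summarize_cohort(results)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(results, file.path(cfg$out_dir, "classifications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(results = results, summary = summary))
}

#' Design reporter constructs for one gene
#'
#' Runs [design_constructs()] for the named gene and writes
#' `constructs_<gene>.tsv` (one row per construct and transcript, with the
#' predicted expression indicator) and `arms_<gene>.fa` (homology arms for
#' every edit of every construct).
#'
#' @param cfg A [run_config()].
#' @param gene_id Gene to design for.
#' @param reporter_payload Reporter CDS (default
#'   [default_reporter_payload()]).
#' @return Invisibly, the [design_constructs()] result.
#' @export
run_design <- function(cfg, gene_id,
                       reporter_payload = default_reporter_payload()) {
  genome <- read_genome(cfg$genome)
  genes <- parse_gene_models(cfg$annotation, genome)
  if (!gene_id %in% names(genes)) stop("unknown gene: ", gene_id)
  g <- genes[[gene_id]]
  des <- design_constructs(g, genome, reporter_payload)
  rows <- list(); arms <- character(0)
  for (cons in des$constructs) {
    for (tid in names(cons$vector))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, construct = cons$label, transcript_id = tid,
        expresses = cons$vector[[tid]], stringsAsFactors = FALSE)
    for (e in cons$edits) {
      ha <- homology_arms(genome, g$chrom, e$position, cfg$arm_length)
      nm <- paste0(cons$label, "_", e$kind, "_", e$position)
      arms[paste0(nm, "_up")] <- ha$upstream
      arms[paste0(nm, "_down")] <- ha$downstream
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(do.call(rbind, rows),
                     file.path(cfg$out_dir,
                               paste0("constructs_", gene_id, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genome(arms, file.path(cfg$out_dir, paste0("arms_", gene_id, ".fa")))
  invisible(des)
}

#' Simulate a synthetic cohort to disk
#'
#' Thin wrapper over [generate_cohort()] writing `genome.fa`,
#' `annotation.gff3`, `evidence.tsv` and `truth.tsv`.
#'
#' @param out_dir Output directory.
#' @param n_genes,mixture,seed,... Passed to [generate_cohort()].
#' @return Invisibly, the generated cohort.
#' @export
run_simulate <- function(out_dir, n_genes, mixture = c(UNIQUE_START = 1),
                         seed = 1L, ...) {
  invisible(generate_cohort(n_genes, mixture, seed, dir = out_dir, ...))
}
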