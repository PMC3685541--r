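# Packaged reference tables from a published curation of alternative
# isoform annotations across the C. elegans transcription-factor gene
# complement, plus loaders for the small synthetic example loci shipped
# with the package.

#' Survey counts of transcription-factor genes by alternative-isoform
#' category
#'
#' The packaged count table from a curated survey of 938 C. elegans
#' transcription-factor genes: how many showed no alternative transcripts,
#' how many alternatives encode the same protein, and how the 197 genes
#' annotated with distinct isoforms distribute over the mechanism/evidence
#' categories.
#'
#' @return data.frame with `key` (machine-readable category), `label`
#'   (original wording) and `n`.
#' @export
isoform_survey_counts <- function() {
  utils::read.delim(system.file("extdata", "tf_isoform_survey_counts.tsv",
                                package = "txiso"),
                    stringsAsFactors = FALSE)
}

#' Aggregate survey counts into mechanism-level totals
#'
#' Reproduces the arithmetic structure of the survey: genes with
#' alternative transcript starts (unique starting exons, strong or weak,
#' plus nested starts), alternative ends, alternative splicing
#' (non-constitutive exons/introns and splice-site selection), multiple
#' mechanisms, and discounted annotations; these partition the genes
#' annotated with distinct isoforms, which together with the
#' no-evidence and same-protein genes account for the whole complement.
#'
#' @param counts A count table as returned by [isoform_survey_counts()].
#' @return Named numeric vector: `alt_starts`, `alt_ends`, `alt_splicing`,
#'   `multiple`, `discounted`, `distinct_isoform_genes`, `total_accounted`.
#' @export
survey_aggregates <- function(counts = isoform_survey_counts()) {
  g <- function(key) counts$n[counts$key == key]
  alt_starts <- g("unique_starting_exon_strong") +
    g("unique_starting_exon_weak") + g("nested_alternative_starts")
  alt_ends <- g("alternative_terminal_exon_strong") +
    g("alternative_terminal_exon_weak")
  alt_splicing <- g("internal_exon_strong") + g("internal_exon_weak") +
    g("internal_intron_strong") + g("internal_intron_weak") +
    g("splice_site_selection_strong") + g("splice_site_selection_weak")
  multiple <- g("multiple_mechanisms_strong") + g("multiple_mechanisms_weak")
  discounted <- g("evidence_considered_invalid")
  distinct <- alt_starts + alt_ends + alt_splicing + multiple + discounted
  total <- g("no_evidence_for_alternative_transcripts") +
    g("alternative_transcripts_encode_same_protein") + distinct
  c(alt_starts = alt_starts, alt_ends = alt_ends,
    alt_splicing = alt_splicing, multiple = multiple,
    discounted = discounted, distinct_isoform_genes = distinct,
    total_accounted = total)
}

#' Table of the transcription-factor genes assayed by reporter fusion
#'
#' The packaged table of the 29 genes whose transcript-specific expression
#' was assayed with seamlessly recombineered reporter fusions: gene names,
#' the annotated mode of alternative-transcript production, the assessment
#' of the supporting evidence and the DNA-binding domain family.
#'
#' @return data.frame with columns `molecular_name`, `genetic_name`,
#'   `annotation`, `assessment`, `comment`, `dna_binding_domain`.
#' @export
assayed_genes <- function() {
  utils::read.delim(system.file("extdata", "tf_genes_assayed.tsv",
                                package = "txiso"),
                    stringsAsFactors = FALSE)
}

#' Study-design counts of the assayed genes
#'
#' @param tbl The table from [assayed_genes()].
#' @return Named numeric vector: total assayed and counts per annotation
#'   class (alternative promoters, non-constitutive exons, non-constitutive
#'   introns, complex).
#' @export
assayed_gene_counts <- function(tbl = assayed_genes()) {
  ann <- tbl$annotation
  c(n_assayed = nrow(tbl),
    alternative_promoters = sum(ann == "Alternative promoters"),
    nonconstitutive_exon = sum(ann == "Exon +/-"),
    nonconstitutive_intron = sum(ann == "Intron +/-"),
    complex = sum(startsWith(ann, "Complex")))
}

#' Load the packaged synthetic example locus
#'
#' A small synthetic gene with three transcripts, each with a unique
#' protein-coding starting exon splicing into a shared downstream chain --
#' the classic alternative-promoter topology. Generated by
#' [generate_gene()] and shipped as plain GFF3 + FASTA.
#'
#' @return List with `gene` (a [gene_model()]) and `genome` (a
#'   `DNAStringSet`).
#' @export
example_unique_start_locus <- function() {
  genome <- read_genome(system.file("extdata", "synthetic_unique_start.fa",
                                    package = "txiso"))
  genes <- parse_gene_models(
    system.file("extdata", "synthetic_unique_start.gff3", package = "txiso"),
    genome)
  list(gene = genes[[1L]], genome = genome)
}
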