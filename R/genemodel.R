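# Gene/transcript data model and coordinate arithmetic.
#
# Conventions used throughout the package:
#  * genomic intervals are 0-based, half-open [start, end) on the plus strand
#    of the reference sequence;
#  * exons of a transcript are stored in transcript (5'->3') order, i.e. in
#    descending genomic order for minus-strand transcripts;
#  * cds_start is the genomic position (0-based) of the first base of the
#    initiation codon, cds_end the genomic position of the last base of the
#    termination codon, both in transcript orientation.

#' Construct a transcript
#'
#' A transcript is an ordered chain of exons on one strand of one reference
#' sequence, optionally with an annotated coding region. Exons are given as a
#' two-column matrix or data.frame of 0-based half-open `[start, end)`
#' intervals in transcript (5'->3') order; for a minus-strand transcript that
#' means descending genomic coordinates.
#'
#' @param id Transcript identifier.
#' @param chrom Reference sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix/data.frame (`start`, `end`), 0-based
#'   half-open, in transcript order.
#' @param cds_start Genomic position (0-based) of the first base of the
#'   initiation codon, or `NA` for a non-coding annotation.
#' @param cds_end Genomic position (0-based) of the last base of the
#'   termination codon, or `NA`.
#' @param trans_spliced Logical flag marking transcripts whose mature 5' end
#'   receives a spliced leader. The leader sequence itself is not modelled.
#' @return An object of class `"Transcript"`.
#' @export
transcript <- function(id, chrom, strand, exons, cds_start = NA_integer_,
                       cds_end = NA_integer_, trans_spliced = FALSE) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  obj <- structure(
    list(id = as.character(id), chrom = as.character(chrom),
         strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         trans_spliced = isTRUE(trans_spliced)),
    class = "Transcript")
  validate_transcript(obj)
  obj
}

validate_transcript <- function(t) {
  ex <- t$exons
  if (nrow(ex) < 1L) stop("transcript '", t$id, "': needs at least one exon")
  if (!t$strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(ex[, "start"] < 0L) || any(ex[, "end"] <= ex[, "start"]))
    stop("transcript '", t$id, "': exons must satisfy 0 <= start < end")
  if (nrow(ex) > 1L) {
    ok <- if (t$strand == "+") all(diff(ex[, "start"]) > 0) &&
            all(ex[-nrow(ex), "end"] <= ex[-1L, "start"])
          else all(diff(ex[, "start"]) < 0) &&
            all(ex[-1L, "end"] <= ex[-nrow(ex), "start"])
    if (!ok) stop("transcript '", t$id,
                  "': exons must be non-overlapping and in transcript order")
  }
  if (!is.na(t$cds_start)) {
    if (!point_in_exons(t, t$cds_start) || !point_in_exons(t, t$cds_end))
      stop("transcript '", t$id, "': CDS endpoints must fall inside exons")
  }
  invisible(t)
}

#' @export
print.Transcript <- function(x, ...) {
  cat(sprintf("Transcript %s (%s%s) %d exon(s), %d nt spliced\n",
              x$id, x$chrom, x$strand, nrow(x$exons), transcript_length(x)))
  invisible(x)
}

#' Construct a gene model
#'
#' @param id Gene identifier.
#' @param transcripts List of [transcript()] objects; all must share the
#'   reference sequence and strand (a locus with transcripts on both strands
#'   is two genes, not one).
#' @param molecular_name,genetic_name Optional display names (e.g. the
#'   sequence-derived and the classical gene name).
#' @return An object of class `"GeneModel"` with a `span` field covering all
#'   transcripts.
#' @export
gene_model <- function(id, transcripts, molecular_name = NA_character_,
                       genetic_name = NA_character_) {
  if (length(transcripts) < 1L) stop("gene '", id, "': needs >= 1 transcript")
  chrom <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strand <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chrom) != 1L)
    stop("gene '", id, "': transcripts on different sequences")
  if (length(strand) != 1L)
    stop("gene '", id, "': transcripts on both strands; mixed-strand loci ",
         "must be modelled as separate genes")
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  span <- c(start = min(vapply(transcripts, function(t) min(t$exons[, "start"]), 0L)),
            end   = max(vapply(transcripts, function(t) max(t$exons[, "end"]), 0L)))
  structure(list(id = as.character(id),
                 molecular_name = as.character(molecular_name),
                 genetic_name = as.character(genetic_name),
                 chrom = chrom, strand = strand,
                 transcripts = transcripts, span = span),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s) [%d, %d) with %d transcript(s): %s\n",
              x$id, x$chrom, x$strand, x$span["start"], x$span["end"],
              length(x$transcripts),
              paste(names(x$transcripts), collapse = ", ")))
  invisible(x)
}

## ---- coordinate helpers -----------------------------------------------

exon_lengths <- function(t) t$exons[, "end"] - t$exons[, "start"]

#' Spliced length of a transcript
#' @param t A [transcript()].
#' @return Integer, the sum of exon lengths.
#' @export
transcript_length <- function(t) sum(exon_lengths(t))

point_in_exons <- function(t, pos) {
  any(t$exons[, "start"] <= pos & pos < t$exons[, "end"])
}

#' Genomic position of the transcript 5' terminus (0-based base position).
#' @param t A [transcript()].
#' @export
tx_start <- function(t) {
  unname(if (t$strand == "+") t$exons[1L, "start"] else t$exons[1L, "end"] - 1L)
}

#' Genomic position of the transcript 3' terminus (0-based base position).
#' @param t A [transcript()].
#' @export
tx_end <- function(t) {
  n <- nrow(t$exons)
  unname(if (t$strand == "+") t$exons[n, "end"] - 1L else t$exons[n, "start"])
}

#' Map a genomic base position to its spliced (transcript) offset
#'
#' @param t A [transcript()].
#' @param pos Genomic 0-based base position; must fall inside an exon.
#' @return 0-based offset of that base in the spliced transcript.
#' @export
genomic_to_spliced <- function(t, pos) {
  ex <- t$exons
  lens <- exon_lengths(t)
  hit <- which(ex[, "start"] <= pos & pos < ex[, "end"])
  if (length(hit) != 1L)
    stop("position ", pos, " not inside an exon of transcript ", t$id)
  before <- if (hit > 1L) sum(lens[seq_len(hit - 1L)]) else 0L
  within <- if (t$strand == "+") pos - ex[hit, "start"]
            else ex[hit, "end"] - 1L - pos
  as.integer(before + within)
}

#' Map a spliced (transcript) offset back to its genomic base position
#'
#' Inverse of [genomic_to_spliced()].
#' @param t A [transcript()].
#' @param offset 0-based spliced offset in `[0, transcript_length(t))`.
#' @export
spliced_to_genomic <- function(t, offset) {
  lens <- exon_lengths(t)
  if (offset < 0L || offset >= sum(lens)) stop("spliced offset out of range")
  cum <- cumsum(lens)
  hit <- which(offset < cum)[1L]
  within <- offset - (if (hit > 1L) cum[hit - 1L] else 0L)
  if (t$strand == "+") as.integer(t$exons[hit, "start"] + within)
  else as.integer(t$exons[hit, "end"] - 1L - within)
}

#' Spliced offset of the initiation codon's first base
#' @param t A coding [transcript()].
#' @export
cds_offset <- function(t) {
  if (is.na(t$cds_start)) stop("transcript ", t$id, " has no annotated CDS")
  genomic_to_spliced(t, t$cds_start)
}

#' Introns of a transcript
#'
#' The gaps between consecutive exons, as genomic `[start, end)` intervals,
#' returned in transcript (5'->3') order. A single-exon transcript has none.
#'
#' @param t A [transcript()].
#' @return Integer matrix with columns `start`, `end`; zero rows when the
#'   transcript has a single exon.
#' @export
introns_of <- function(t) {
  n <- nrow(t$exons)
  out <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  if (n < 2L) return(out)
  if (t$strand == "+") {
    cbind(start = t$exons[-n, "end"], end = t$exons[-1L, "start"])
  } else {
    cbind(start = t$exons[-1L, "end"], end = t$exons[-n, "start"])
  }
}

## junction signature: introns as genomic intervals sorted by start, used for
## exon-chain comparison independent of strand
junction_signature <- function(introns) {
  if (nrow(introns) == 0L) return(character(0))
  ord <- order(introns[, "start"])
  paste(introns[ord, "start"], introns[ord, "end"], sep = "-")
}

## ---- sequence extraction ----------------------------------------------

#' Spliced sequence of a transcript
#'
#' Concatenates the exon sequences in transcript order, reverse-complementing
#' for minus-strand transcripts.
#'
#' @param t A [transcript()].
#' @param genome A named [Biostrings::DNAStringSet] (or named character
#'   vector) holding the reference sequences.
#' @return A character string of length [transcript_length()].
#' @export
spliced_sequence <- function(t, genome) {
  chromseq <- genome_sequence(genome, t$chrom)
  if (max(t$exons[, "end"]) > nchar(chromseq))
    stop("exon of transcript ", t$id, " extends beyond the end of sequence ",
         t$chrom)
  parts <- substring(chromseq, t$exons[, "start"] + 1L, t$exons[, "end"])
  if (t$strand == "-") parts <- revcomp(parts)
  paste(parts, collapse = "")
}

genome_sequence <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("sequence '", chrom, "' not in genome")
    as.character(genome[[chrom]])
  } else {
    if (!chrom %in% names(genome)) stop("sequence '", chrom, "' not in genome")
    genome[[chrom]]
  }
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Coding (CDS) spliced sequence of a transcript
#'
#' The spliced sequence from the first base of the initiation codon through
#' the last base of the termination codon.
#' @param t A coding [transcript()].
#' @param genome Reference sequences as for [spliced_sequence()].
#' @export
cds_sequence <- function(t, genome) {
  s <- spliced_sequence(t, genome)
  a <- cds_offset(t)
  b <- genomic_to_spliced(t, t$cds_end)
  substring(s, a + 1L, b + 1L)
}
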