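# Translation-based checks: codon scanning, premature-stop / NMD assessment,
# upstream ORF scanning and reading-frame comparison between transcripts.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codons_from <- function(seq, start_offset) {
  n <- nchar(seq)
  starts <- seq.int(start_offset + 1L, n, by = 3L)
  starts <- starts[starts + 2L <= n]
  substring(seq, starts, starts + 2L)
}

#' Translate from an initiation codon to the first stop
#'
#' Scans the standard genetic code codon-by-codon from `start_offset` to the
#' first termination codon (TAA/TAG/TGA) or the end of the sequence.
#'
#' @param seq Nucleotide string (spliced transcript sequence).
#' @param start_offset 0-based offset of the initiation codon; the three
#'   bases there must be `ATG`.
#' @return A list with `protein_length` (amino acids, the initial Met
#'   included, the stop excluded), `stop_offset` (0-based offset of the first
#'   base of the stop codon, `NA` when none) and `runs_off_end`.
#' @export
translate_from <- function(seq, start_offset) {
  if (substring(seq, start_offset + 1L, start_offset + 3L) != "ATG")
    stop("no ATG at offset ", start_offset)
  cods <- codons_from(seq, start_offset)
  hit <- which(cods %in% STOP_CODONS)
  if (length(hit) == 0L) {
    list(protein_length = length(cods), stop_offset = NA_integer_,
         runs_off_end = TRUE)
  } else {
    k <- hit[1L]
    list(protein_length = k - 1L,
         stop_offset = as.integer(start_offset + (k - 1L) * 3L),
         runs_off_end = FALSE)
  }
}

#' Assess a transcript for nonsense-mediated decay candidacy
#'
#' Translation is scanned from the annotated initiation codon of the spliced
#' transcript; the stop actually reached is classified as premature when it
#' lies at least `rule_distance` bases 5' of the final exon-exon junction in
#' spliced coordinates (the classical 50-nt rule). Single-exon transcripts
#' have no junction and are never flagged.
#'
#' @param t A coding [transcript()].
#' @param genome Reference sequences as for [spliced_sequence()].
#' @param rule_distance Minimum distance (bases) from the 3' end of the stop
#'   codon to the last junction for the stop to count as premature.
#' @return A list with `is_ptc` and `distance_to_last_junction` (signed;
#'   positive when the stop is 5' of the junction; `NA` for single-exon
#'   transcripts or when translation runs off the end).
#' @export
assess_nmd <- function(t, genome, rule_distance = 50L) {
  if (is.na(t$cds_start)) stop("transcript ", t$id, " has no annotated CDS")
  if (nrow(t$exons) < 2L)
    return(list(is_ptc = FALSE, distance_to_last_junction = NA_integer_))
  s <- spliced_sequence(t, genome)
  tr <- translate_from(s, cds_offset(t))
  if (tr$runs_off_end)
    return(list(is_ptc = FALSE, distance_to_last_junction = NA_integer_))
  lens <- exon_lengths(t)
  last_junction <- sum(lens) - lens[length(lens)]  # spliced offset of final exon start
  dist <- as.integer(last_junction - (tr$stop_offset + 3L))
  list(is_ptc = dist >= rule_distance, distance_to_last_junction = dist)
}

#' Scan the 5' UTR of a transcript for upstream ATGs
#'
#' Every ATG in the spliced 5' UTR is reported. An upstream ATG is deemed to
#' block translation of the main ORF when it is out of frame with the main
#' initiation codon and its own reading frame contains no stop codon before
#' the main start, so that ribosomes initiating there would read through the
#' main ATG out of frame with no chance to terminate and reinitiate.
#'
#' @param t A coding [transcript()] whose initiation codon lies 3' of the
#'   transcript start. A transcript with an empty 5' UTR yields zero rows.
#' @param genome Reference sequences as for [spliced_sequence()].
#' @return data.frame with columns `offset` (spliced, 0-based),
#'   `in_frame_with_main`, `blocks_main`.
#' @export
scan_uorfs <- function(t, genome) {
  empty <- data.frame(offset = integer(0), in_frame_with_main = logical(0),
                      blocks_main = logical(0))
  if (is.na(t$cds_start)) stop("transcript ", t$id, " has no annotated CDS")
  main <- cds_offset(t)
  if (main == 0L) return(empty)
  s <- spliced_sequence(t, genome)
  utr <- substring(s, 1L, main)
  hits <- gregexpr("ATG", utr, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(empty)
  offs <- as.integer(hits) - 1L
  out <- lapply(offs, function(u) {
    in_frame <- (main - u) %% 3L == 0L
    cods <- codons_from(s, u)
    stop_idx <- which(cods %in% STOP_CODONS)
    stop_before_main <- length(stop_idx) > 0L &&
      (u + (stop_idx[1L] - 1L) * 3L) < main
    data.frame(offset = u, in_frame_with_main = in_frame,
               blocks_main = !in_frame && !stop_before_main)
  })
  do.call(rbind, out)
}

#' Compare the reading frames of two transcripts over a shared terminal exon
#'
#' Both transcripts must end at the same genomic 3' boundary. The reading
#' frame phase of each transcript is evaluated at a genomic base common to
#' both final exons and the difference is returned mod 3; 0 means the shared
#' terminal exon is translated in the same frame (as after a splice-site
#' shift that is a multiple of three bases).
#'
#' @param t1,t2 Coding [transcript()]s sharing their final exon's 3'
#'   boundary.
#' @return Integer in `{0, 1, 2}`: the phase of `t1` minus the phase of
#'   `t2`, mod 3, at the first shared base of the terminal exons.
#' @export
compare_terminal_frames <- function(t1, t2) {
  e1 <- t1$exons[nrow(t1$exons), ]; e2 <- t2$exons[nrow(t2$exons), ]
  shared_3p <- if (t1$strand == "+") e1["end"] == e2["end"]
               else e1["start"] == e2["start"]
  if (t1$strand != t2$strand || t1$chrom != t2$chrom || !shared_3p)
    stop("transcripts do not share a terminal exon 3' boundary: not comparable")
  # most 3' of the two final-exon 5' boundaries = first base common to both
  common <- if (t1$strand == "+") max(e1["start"], e2["start"])
            else min(e1["end"], e2["end"]) - 1L
  phase <- function(t, pos) (genomic_to_spliced(t, pos) - cds_offset(t)) %% 3L
  as.integer((phase(t1, common) - phase(t2, common)) %% 3L)
}
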