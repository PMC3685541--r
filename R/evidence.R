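# Transcript-support records (EST / RT-PCR / ORFeome-clone alignments) and
# evidence grading. A record is an aligned exon chain with completeness
# flags; grading follows the strong / weak / unsupported scheme: a transcript
# is strongly supported when multiple independent, artifact-free ESTs match
# it, weakly supported when only few ESTs or only PCR/clone records do, and
# unsupported otherwise. Likely artifacts are flagged: 5'-truncated cDNAs
# (incomplete first-strand synthesis), unspliced genomic reads (primary
# transcript or genomic contamination) and primer-encoded starts.

SUPPORT_SOURCES <- c("EST", "RT_PCR", "ORFEOME_CLONE")
ARTIFACT_FLAGS <- c("TRUNCATED_5P", "UNSPLICED", "PRIMER_DERIVED")
EVIDENCE_GRADES <- c("STRONG", "WEAK", "UNSUPPORTED")

#' Construct a table of transcript-support records
#'
#' @param id Record identifiers.
#' @param source One of `"EST"`, `"RT_PCR"`, `"ORFEOME_CLONE"`.
#' @param chrom,strand Alignment location.
#' @param blocks Character encoding of the aligned exon chain as
#'   `"start-end;start-end;..."` genomic 0-based half-open intervals in
#'   ascending genomic order.
#' @param library Library-of-origin key; records from distinct libraries are
#'   treated as independent.
#' @param five_prime_complete Whether the 5' end of the read reflects the
#'   true transcript 5' end.
#' @param primer_defined_start Whether the 5' end was dictated by a PCR
#'   primer rather than observed.
#' @return A `data.frame` with one row per record.
#' @export
support_records <- function(id, source, chrom, strand, blocks, library,
                            five_prime_complete = TRUE,
                            primer_defined_start = FALSE) {
  stopifnot(all(source %in% SUPPORT_SOURCES))
  if (length(id) == 0L) {
    five_prime_complete <- logical(0)
    primer_defined_start <- logical(0)
  }
  data.frame(id = as.character(id), source = source, chrom = chrom,
             strand = strand, blocks = blocks, library = as.character(library),
             five_prime_complete = five_prime_complete,
             primer_defined_start = primer_defined_start,
             stringsAsFactors = FALSE)
}

#' Decode a record's block string into an interval matrix
#' @param blocks A single `"start-end;start-end"` string.
#' @return Integer matrix with columns `start`, `end`, ascending genomic
#'   order.
#' @export
decode_blocks <- function(blocks) {
  parts <- strsplit(strsplit(blocks, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("start", "end")
  m[order(m[, "start"]), , drop = FALSE]
}

encode_blocks <- function(m) {
  m <- m[order(m[, "start"]), , drop = FALSE]
  paste(paste(m[, "start"], m[, "end"], sep = "-"), collapse = ";")
}

#' Read / write an evidence table
#'
#' Tab-separated with the columns of [support_records()].
#' @param path TSV path.
#' @return For `read_evidence`, a support-record data.frame.
#' @export
read_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(library = "character"))
  df$five_prime_complete <- as.logical(df$five_prime_complete)
  df$primer_defined_start <- as.logical(df$primer_defined_start)
  df
}

#' @rdname read_evidence
#' @param records A support-record data.frame.
#' @export
write_evidence <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

record_junctions <- function(blocks_m) {
  n <- nrow(blocks_m)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = blocks_m[-n, "end"], end = blocks_m[-1L, "start"])
}

## junctions of a transcript in ascending genomic order
tx_junctions_sorted <- function(t) {
  j <- introns_of(t)
  j[order(j[, "start"]), , drop = FALSE]
}

## does the record match the transcript: every record junction matches a
## consecutive run of transcript junctions within tolerance, and the
## terminal blocks stay inside the corresponding exons
record_supports <- function(blocks_m, t, tolerance = 0L) {
  rj <- record_junctions(blocks_m)
  if (nrow(rj) == 0L) {
    # junctionless: supported iff contained in a single exon
    return(any(t$exons[, "start"] - tolerance <= blocks_m[1L, "start"] &
               blocks_m[1L, "end"] <= t$exons[, "end"] + tolerance))
  }
  tj <- tx_junctions_sorted(t)
  k <- nrow(rj); m <- nrow(tj)
  if (k > m) return(FALSE)
  exs <- t$exons[order(t$exons[, "start"]), , drop = FALSE]
  for (off in 0:(m - k)) {
    seg <- tj[off + seq_len(k), , drop = FALSE]
    if (!all(abs(seg[, "start"] - rj[, "start"]) <= tolerance &
             abs(seg[, "end"] - rj[, "end"]) <= tolerance)) next
    # terminal blocks must lie within the flanking exons (contiguous sub-path)
    first_ok <- blocks_m[1L, "start"] >= exs[off + 1L, "start"] - tolerance
    last_ok <- blocks_m[nrow(blocks_m), "end"] <= exs[off + k + 1L, "end"] + tolerance
    if (first_ok && last_ok) return(TRUE)
  }
  FALSE
}

## does a junctionless record span a full intron of any transcript?
record_is_unspliced <- function(blocks_m, gene) {
  if (nrow(record_junctions(blocks_m)) > 0L) return(FALSE)
  s <- blocks_m[1L, "start"]; e <- blocks_m[1L, "end"]
  any(vapply(gene$transcripts, function(t) {
    intr <- introns_of(t)
    nrow(intr) > 0L && any(intr[, "start"] >= s & intr[, "end"] <= e)
  }, TRUE))
}

#' Assign support records to the transcripts they are compatible with
#'
#' A record supports a transcript when every splice junction of the record
#' matches a consecutive run of the transcript's junctions within
#' `tolerance` and the record is a contiguous sub-path of the transcript's
#' exon chain. Records compatible with several transcripts are assigned to
#' all of them; junction-bearing records compatible with none are returned
#' unassigned. Artifact flags are attached per record: `TRUNCATED_5P`
#' (incomplete 5' end), `UNSPLICED` (junctionless record spanning an
#' annotated intron, i.e. the unspliced primary transcript or genomic DNA)
#' and `PRIMER_DERIVED` (5' end dictated by a primer).
#'
#' @param records A support-record data.frame ([support_records()]).
#' @param gene A [gene_model()].
#' @param tolerance Junction-match tolerance in bases.
#' @return A list with `assignments` (named list: transcript id -> record
#'   ids), `unassigned` (record ids) and `record_flags` (data.frame `id`,
#'   `truncated_5p`, `unspliced`, `primer_derived`).
#' @export
assign_support <- function(records, gene, tolerance = 0L) {
  records <- records[records$chrom == gene$chrom &
                     records$strand == gene$strand, , drop = FALSE]
  assignments <- stats::setNames(
    vector("list", length(gene$transcripts)), names(gene$transcripts))
  unassigned <- character(0)
  flags <- data.frame(id = character(0), truncated_5p = logical(0),
                      unspliced = logical(0), primer_derived = logical(0))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    bm <- decode_blocks(rec$blocks)
    unspliced <- record_is_unspliced(bm, gene)
    flags <- rbind(flags, data.frame(
      id = rec$id, truncated_5p = !rec$five_prime_complete,
      unspliced = unspliced, primer_derived = rec$primer_defined_start))
    hit <- FALSE
    for (t in gene$transcripts) {
      if (record_supports(bm, t, tolerance)) {
        assignments[[t$id]] <- c(assignments[[t$id]], rec$id)
        hit <- TRUE
      }
    }
    if (!hit) unassigned <- c(unassigned, rec$id)
  }
  list(assignments = assignments, unassigned = unassigned,
       record_flags = flags, records = records)
}

#' Grade the evidence for each transcript
#'
#' `n_independent` counts supporting EST records with distinct library keys
#' and no artifact flags. A transcript grades `STRONG` when `n_independent`
#' is at least `strong_threshold` ("multiple independent ESTs"), `WEAK` when
#' it has any support falling short of that (few ESTs, artifact-flagged
#' ESTs, RT-PCR or ORFeome-clone records), and `UNSUPPORTED` with no support
#' at all. The `PRIMER_DERIVED` flag is set when the only records defining
#' the transcript's 5' start have primer-encoded starts.
#'
#' @param assignment Result of [assign_support()].
#' @param gene The [gene_model()] the assignment was computed for.
#' @param strong_threshold Minimum independent EST count for `STRONG`.
#' @return data.frame with one row per transcript: `transcript_id`, `grade`,
#'   `n_independent`, `n_support`, and logical artifact-flag columns
#'   `truncated_5p`, `unspliced`, `primer_derived`.
#' @export
grade_evidence <- function(assignment, gene, strong_threshold = 2L) {
  recs <- assignment$records
  fl <- assignment$record_flags
  out <- lapply(names(gene$transcripts), function(tid) {
    ids <- assignment$assignments[[tid]]
    sup <- recs[recs$id %in% ids, , drop = FALSE]
    supfl <- fl[fl$id %in% ids, , drop = FALSE]
    clean_est <- sup$source == "EST" & sup$five_prime_complete &
      !supfl$unspliced[match(sup$id, supfl$id)] & !sup$primer_defined_start
    n_independent <- length(unique(sup$library[clean_est]))
    grade <- if (n_independent >= strong_threshold) "STRONG"
             else if (nrow(sup) > 0L) "WEAK" else "UNSUPPORTED"
    # start-defining records: 5'-complete records whose 5' block overlaps the
    # transcript's first exon
    t <- gene$transcripts[[tid]]
    fe <- t$exons[1L, ]
    startdef <- vapply(seq_len(nrow(sup)), function(i) {
      bm <- decode_blocks(sup$blocks[i])
      fb <- if (t$strand == "+") bm[1L, , drop = FALSE]
            else bm[nrow(bm), , drop = FALSE]
      sup$five_prime_complete[i] &&
        interval_overlap(fb[, "start"], fb[, "end"], fe["start"], fe["end"]) > 0L
    }, TRUE)
    primer_derived <- any(startdef) && all(sup$primer_defined_start[startdef])
    data.frame(transcript_id = tid, grade = grade,
               n_independent = n_independent, n_support = nrow(sup),
               truncated_5p = any(supfl$truncated_5p),
               unspliced = all(supfl$unspliced) && nrow(supfl) > 0L,
               primer_derived = primer_derived,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
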