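# In-silico recombineering: seamless edits to a locus (reporter insertions,
# single-base insertions, substitutions, small deletions), per-transcript
# prediction of translational-reporter expression, and design of construct
# sets that distinguish transcripts. Splicing is assumed unchanged by an
# edit unless the edit touches a splice dinucleotide, in which case a
# warning is raised rather than a silent prediction.

EDIT_KINDS <- c("REPORTER_INSERTION", "NT_INSERTION", "SUBSTITUTION",
                "DELETION")
REPORTER_REASONS <- c("IN_FRAME", "FRAMESHIFTED_UPSTREAM", "PREMATURE_STOP",
                      "REPORTER_NOT_IN_TRANSCRIPT", "SPLICED_OUT")

#' Construct a genome edit
#'
#' Coordinates refer to the unedited plus strand. An insertion places its
#' payload immediately before the base at `position`; a substitution
#' replaces `nchar(payload)` bases starting at `position`; a deletion
#' removes `del_length` bases starting at `position`.
#'
#' @param kind One of `"REPORTER_INSERTION"`, `"NT_INSERTION"`,
#'   `"SUBSTITUTION"`, `"DELETION"`.
#' @param position 0-based genomic position.
#' @param payload Plus-strand nucleotide string (empty for deletions). A
#'   reporter payload must be a multiple of three bases with no frame-0
#'   internal stop codon.
#' @param del_length Number of bases removed (deletions only).
#' @return A list of class `"Edit"`.
#' @export
edit_op <- function(kind, position, payload = "", del_length = 0L) {
  kind <- match.arg(kind, EDIT_KINDS)
  if (kind == "REPORTER_INSERTION") {
    if (nchar(payload) %% 3L != 0L)
      stop("reporter payload length must be a multiple of 3")
    cods <- codons_from(payload, 0L)
    if (any(cods %in% STOP_CODONS))
      stop("reporter payload must not contain an in-frame stop codon")
  }
  if (kind == "DELETION" && del_length <= 0L)
    stop("deletion needs del_length > 0")
  structure(list(kind = kind, position = as.integer(position),
                 payload = toupper(payload),
                 del_length = as.integer(del_length)),
            class = "Edit")
}

edit_footprint <- function(e) {
  switch(e$kind,
         REPORTER_INSERTION = ,
         NT_INSERTION = c(e$position, e$position),
         SUBSTITUTION = c(e$position, e$position + nchar(e$payload)),
         DELETION = c(e$position, e$position + e$del_length))
}

edit_delta <- function(e) {
  switch(e$kind,
         REPORTER_INSERTION = ,
         NT_INSERTION = nchar(e$payload),
         SUBSTITUTION = 0L,
         DELETION = -e$del_length)
}

## shift a coordinate through one edit; `exclusive` marks half-open interval
## ends (which do not move when the edit sits exactly at them)
shift_coord <- function(c0, e, exclusive = FALSE) {
  p <- e$position
  d <- edit_delta(e)
  if (d > 0L) {  # insertion
    moves <- if (exclusive) c0 > p else c0 >= p
    if (moves) c0 + d else c0
  } else if (d < 0L) {  # deletion of [p, p - d)
    k <- -d
    if (c0 <= p) c0 else c0 - min(k, c0 - p)
  } else c0
}

#' Apply a set of edits to a gene and its genome
#'
#' The sequence is modified and every annotation coordinate 3' (in genomic
#' terms) of each edit is shifted by the edit's net length change, so exon
#' boundaries keep their position relative to the local sequence. A payload
#' inserted inside an exon becomes part of that exon; inserted inside an
#' intron it stays intronic. Overlapping edits are an error; an edit
#' touching a splice dinucleotide (the GT/AG ends of an intron) raises a
#' splice-disruption warning because the splicing outcome is then not
#' predictable.
#'
#' @param g A [gene_model()].
#' @param genome Reference sequences (named character or `DNAStringSet`).
#' @param edits List of [edit_op()]s (at most one `REPORTER_INSERTION`).
#' @return List with `gene` (edited [gene_model()]), `genome` (edited, as a
#'   named character vector) and `reporter_span` (`c(start, end)` of the
#'   reporter payload in edited coordinates, or `NULL`).
#' @export
apply_edits <- function(g, genome, edits) {
  seqs <- stats::setNames(
    lapply(if (methods::is(genome, "DNAStringSet")) names(genome)
           else names(genome),
           function(nm) genome_sequence(genome, nm)),
    if (methods::is(genome, "DNAStringSet")) names(genome) else names(genome))
  if (length(edits) == 0L)
    return(list(gene = g, genome = unlist(seqs), reporter_span = NULL))

  fps <- t(vapply(edits, edit_footprint, integer(2L)))
  ord <- order(fps[, 1L])
  if (any(duplicated(fps[, 1L])) ||
      any(fps[ord, 2L][-length(ord)] > fps[ord, 1L][-1L]))
    stop("overlapping edits")

  # splice-dinucleotide check against the unedited annotation
  for (t in g$transcripts) {
    intr <- introns_of(t)
    for (i in seq_len(nrow(intr))) {
      dinucs <- rbind(c(intr[i, "start"], intr[i, "start"] + 2L),
                      c(intr[i, "end"] - 2L, intr[i, "end"]))
      for (e in edits) {
        fp <- edit_footprint(e)
        hit <- if (fp[1L] == fp[2L])  # insertion point: disrupts only between
          any(dinucs[, 1L] < fp[1L] & fp[1L] < dinucs[, 2L])
        else any(fp[1L] < dinucs[, 2L] & dinucs[, 1L] < fp[2L])
        if (hit)
          warning("edit at ", e$position, " touches a splice dinucleotide ",
                  "of transcript ", t$id, "; splicing outcome unpredictable")
      }
    }
  }

  chrom <- g$chrom
  s <- seqs[[chrom]]
  for (e in edits[rev(ord)]) {  # apply right-to-left so positions stay valid
    p <- e$position
    s <- switch(e$kind,
      REPORTER_INSERTION = ,
      NT_INSERTION = paste0(substring(s, 1L, p), e$payload,
                            substring(s, p + 1L)),
      SUBSTITUTION = paste0(substring(s, 1L, p), e$payload,
                            substring(s, p + nchar(e$payload) + 1L)),
      DELETION = paste0(substring(s, 1L, p),
                        substring(s, p + e$del_length + 1L)))
  }
  seqs[[chrom]] <- s

  shift_all <- function(c0, exclusive = FALSE) {
    for (e in edits) c0 <- shift_coord(c0, e, exclusive)
    c0
  }
  txs <- lapply(g$transcripts, function(t) {
    ex <- cbind(start = vapply(t$exons[, "start"], shift_all, 0L),
                end = vapply(t$exons[, "end"], shift_all, 0L,
                             exclusive = TRUE))
    transcript(t$id, t$chrom, t$strand, ex,
               if (is.na(t$cds_start)) NA_integer_ else shift_all(t$cds_start),
               if (is.na(t$cds_end)) NA_integer_ else shift_all(t$cds_end),
               t$trans_spliced)
  })
  g2 <- gene_model(g$id, txs, g$molecular_name, g$genetic_name)

  rep_edit <- Filter(function(e) e$kind == "REPORTER_INSERTION", edits)
  if (length(rep_edit) > 1L) stop("at most one REPORTER_INSERTION per edit set")
  reporter_span <- NULL
  if (length(rep_edit) == 1L) {
    e <- rep_edit[[1L]]
    others <- Filter(function(o) !identical(o, e), edits)
    p <- e$position
    for (o in others) p <- shift_coord(p, o)
    reporter_span <- c(start = p, end = p + nchar(e$payload))
  }
  list(gene = g2, genome = unlist(seqs), reporter_span = reporter_span)
}

#' Predict reporter expression per transcript
#'
#' For each transcript of the edited gene the reporter is located relative
#' to the transcript's structure and translation is scanned from the
#' transcript's annotated initiation codon:
#' * `SPLICED_OUT` - the reporter lies in an intron of the transcript;
#' * `REPORTER_NOT_IN_TRANSCRIPT` - outside the transcript's exons, or 5' of
#'   (not downstream of) its initiation codon;
#' * `IN_FRAME` - translation reaches the reporter in frame 0 with no prior
#'   stop and traverses it entirely: the reporter is expressed;
#' * `PREMATURE_STOP` - a stop codon intervenes before the reporter;
#' * `FRAMESHIFTED_UPSTREAM` - the reporter is reached out of frame (an
#'   upstream insertion/deletion or alternative splice shifted the frame).
#'
#' @param g Edited [gene_model()] from [apply_edits()].
#' @param genome Edited genome from [apply_edits()].
#' @param reporter_span `c(start, end)` of the reporter in edited
#'   coordinates.
#' @return data.frame: `transcript_id`, `expresses`, `reason`.
#' @export
predict_reporter <- function(g, genome, reporter_span) {
  if (is.null(reporter_span)) stop("no reporter insertion was applied")
  rs <- reporter_span[[1L]]; re <- reporter_span[[2L]]
  plus <- g$strand == "+"
  rows <- lapply(g$transcripts, function(t) {
    out <- function(reason) data.frame(
      transcript_id = t$id, expresses = reason == "IN_FRAME",
      reason = reason, stringsAsFactors = FALSE)
    span <- c(min(t$exons[, "start"]), max(t$exons[, "end"]))
    fully_exonic <- any(t$exons[, "start"] <= rs & re <= t$exons[, "end"])
    if (!fully_exonic) {
      inside_span <- rs >= span[1L] && re <= span[2L]
      return(out(if (inside_span) "SPLICED_OUT" else "REPORTER_NOT_IN_TRANSCRIPT"))
    }
    if (is.na(t$cds_start)) return(out("REPORTER_NOT_IN_TRANSCRIPT"))
    first_base <- if (plus) rs else re - 1L
    r0 <- genomic_to_spliced(t, first_base)
    co <- cds_offset(t)
    if (r0 < co + 3L) return(out("REPORTER_NOT_IN_TRANSCRIPT"))
    s <- spliced_sequence(t, genome)
    tr <- tryCatch(translate_from(s, co), error = function(e) NULL)
    if (is.null(tr)) return(out("PREMATURE_STOP"))  # start codon destroyed
    in_frame <- (r0 - co) %% 3L == 0L
    stop_before <- !tr$runs_off_end && tr$stop_offset < r0
    if (stop_before) return(out("PREMATURE_STOP"))
    if (in_frame) return(out("IN_FRAME"))
    out("FRAMESHIFTED_UPSTREAM")
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Extract homology arms flanking a position
#'
#' The two `arm_length`-base sequences directly 5' and 3' of `position`,
#' used to target a seamless insertion at that point.
#'
#' @param genome Reference sequences.
#' @param chrom Sequence name.
#' @param position 0-based genomic insertion point; must be at least
#'   `arm_length` from both sequence ends.
#' @param arm_length Arm length in bases (default 50).
#' @param strand Orientation of the returned arms; for `"-"` the arms are
#'   reverse-complemented and swapped so `upstream` is 5' in transcript
#'   orientation.
#' @return List with `upstream` and `downstream` arm sequences.
#' @export
homology_arms <- function(genome, chrom, position, arm_length = 50L,
                          strand = "+") {
  s <- genome_sequence(genome, chrom)
  if (position < arm_length || position + arm_length > nchar(s))
    stop("position too close to the sequence end for ", arm_length,
         "-base homology arms")
  left <- substring(s, position - arm_length + 1L, position)
  right <- substring(s, position + 1L, position + arm_length)
  if (strand == "-") list(upstream = revcomp(right), downstream = revcomp(left))
  else list(upstream = left, downstream = right)
}

#' Enumerate and select reporter constructs that distinguish transcripts
#'
#' Candidate constructs follow the study design for seamless reporter
#' tagging: the reporter inserted immediately after each distinct
#' initiation codon (optionally together with a single-base insertion just
#' 5' of that codon, to frameshift translation arriving from transcripts
#' starting further upstream), the reporter inserted immediately before
#' each distinct termination codon, and terminal fusions combined with a
#' single-base insertion in the middle of each optional (cassette) exon or
#' retained intron to knock out transcripts that include it. Each
#' candidate's per-transcript expression indicator vector is computed with
#' [predict_reporter()]; candidates with identical vectors are collapsed
#' (terminal fusions preferred) and all-negative candidates dropped.
#' Transcript pairs whose indicator rows coincide across all candidates are
#' reported as inseparable.
#'
#' @param g A [gene_model()].
#' @param genome Reference sequences.
#' @param reporter_payload Reporter coding sequence (multiple of 3, no
#'   frame-0 stop).
#' @return List with `constructs` (list of `label`, `edits`, `vector`) and
#'   `inseparable` (list of transcript-id groups indistinguishable by any
#'   candidate).
#' @export
design_constructs <- function(g, genome, reporter_payload) {
  plus <- g$strand == "+"
  payload_genomic <- if (plus) reporter_payload else revcomp(reporter_payload)
  txs <- g$transcripts
  candidates <- list()
  add <- function(label, priority, edits)
    candidates[[length(candidates) + 1L]] <<-
      list(label = label, priority = priority, edits = edits)

  # start-tagged fusions, one per distinct initiation codon
  starts <- unique(stats::na.omit(vapply(txs, `[[`, 0L, "cds_start")))
  for (cs in starts) {
    tids <- names(txs)[vapply(txs, function(t)
      isTRUE(t$cds_start == cs), TRUE)]
    p <- if (plus) cs + 3L else cs - 2L
    add(paste0("start_", tids[1L]), 2L,
        list(edit_op("REPORTER_INSERTION", p, payload_genomic)))
    # frameshift variant when another transcript translates through this codon
    upstream_tx <- any(vapply(txs, function(o) {
      !o$id %in% tids && !is.na(o$cds_start) && point_in_exons(o, cs) &&
        (if (plus) o$cds_start < cs else o$cds_start > cs)
    }, TRUE))
    if (upstream_tx) {
      pfs <- if (plus) cs else cs + 1L
      add(paste0("start_", tids[1L], "_fs"), 3L,
          list(edit_op("REPORTER_INSERTION", p, payload_genomic),
               edit_op("NT_INSERTION", pfs, "C")))
    }
  }

  # terminal fusions, one per distinct termination codon
  stops <- unique(stats::na.omit(vapply(txs, `[[`, 0L, "cds_end")))
  for (ce in stops) {
    tids <- names(txs)[vapply(txs, function(t)
      isTRUE(t$cds_end == ce), TRUE)]
    p <- if (plus) ce - 2L else ce + 3L
    add(paste0("terminal_", tids[1L]), 1L,
        list(edit_op("REPORTER_INSERTION", p, payload_genomic)))
    # knockout variants: +1 into each optional exon / retained intron
    calls <- detect_mechanisms(g)
    opt <- calls[calls$mechanism %in% c("CASSETTE_EXON", "RETAINED_INTRON"), ,
                 drop = FALSE]
    for (i in seq_len(nrow(opt))) {
      if (opt$mechanism[i] == "CASSETTE_EXON") {
        t1 <- txs[[opt$t1[i]]]
        e <- t1$exons[opt$exon_index[i], ]
      } else {
        t1 <- txs[[opt$t1[i]]]
        e <- introns_of(t1)[opt$intron_index[i], ]
      }
      mid <- as.integer((e["start"] + e["end"]) %/% 2L)
      add(paste0("terminal_", tids[1L], "_ko", i), 4L,
          list(edit_op("REPORTER_INSERTION", p, payload_genomic),
               edit_op("NT_INSERTION", mid, "C")))
    }
  }

  # indicator vectors
  for (i in seq_along(candidates)) {
    ed <- suppressWarnings(apply_edits(g, genome, candidates[[i]]$edits))
    pr <- predict_reporter(ed$gene, ed$genome, ed$reporter_span)
    candidates[[i]]$vector <- stats::setNames(pr$expresses, pr$transcript_id)
  }

  # collapse identical vectors (prefer terminal > start > variants), drop
  # all-negative candidates
  keep <- list()
  seen <- character(0)
  for (cand in candidates[order(vapply(candidates, `[[`, 0L, "priority"))]) {
    key <- paste(as.integer(cand$vector), collapse = "")
    if (!any(cand$vector) || key %in% seen) next
    seen <- c(seen, key)
    keep[[length(keep) + 1L]] <- cand[c("label", "edits", "vector")]
  }

  # inseparable transcript groups: identical rows across all candidates
  profiles <- vapply(names(txs), function(tid)
    paste(vapply(candidates, function(cand)
      as.integer(cand$vector[[tid]]), 0L), collapse = ""), "")
  groups <- split(names(txs), profiles)
  inseparable <- unname(Filter(function(gp) length(gp) > 1L, groups))

  list(constructs = keep, inseparable = inseparable)
}
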