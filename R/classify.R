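# Gene-level classification: combine mechanism calls, evidence grades and
# translation checks into a single category per gene, mirroring the taxonomy
# used in curated surveys of alternative-isoform annotations, and apply the
# discount rules that remove implausible alternatives (blocking upstream
# ORFs, alternative reading frames on single-record support, annotations
# that are really the unspliced primary transcript, and PTC/NMD-doomed
# alternatives).

CATEGORIES <- c(
  "NO_ALTERNATIVE", "SAME_PROTEIN",
  "UNIQUE_START_STRONG", "UNIQUE_START_WEAK", "NESTED_START",
  "ALT_TERMINAL_STRONG", "ALT_TERMINAL_WEAK",
  "CASSETTE_STRONG", "CASSETTE_WEAK",
  "RETAINED_INTRON_STRONG", "RETAINED_INTRON_WEAK",
  "SPLICE_SHIFT_STRONG", "SPLICE_SHIFT_WEAK",
  "MULTIPLE_STRONG", "MULTIPLE_WEAK", "DISCOUNTED")

DISCOUNT_REASONS <- c("BLOCKING_UORF", "WRONG_FRAME", "UNSPLICED_PRIMARY",
                      "NO_PRODUCTIVE_ALTERNATIVE")

#' Default classification parameters
#'
#' @param strong_threshold Independent-EST count for a STRONG grade.
#' @param tolerance Junction-match tolerance (bases).
#' @param nmd_distance Premature-stop distance for the NMD rule (bases).
#' @param min_overlap Disqualifying first-exon overlap for unique starts.
#' @return A named list of parameters.
#' @export
classify_config <- function(strong_threshold = 2L, tolerance = 0L,
                            nmd_distance = 50L, min_overlap = 1L) {
  stopifnot(strong_threshold > 0L, tolerance >= 0L, nmd_distance > 0L,
            min_overlap > 0L)
  list(strong_threshold = strong_threshold, tolerance = tolerance,
       nmd_distance = nmd_distance, min_overlap = min_overlap)
}

#' Do all transcripts of a gene encode the same protein?
#'
#' True when every transcript yields an identical spliced CDS sequence, i.e.
#' the alternatives differ only in untranslated regions.
#'
#' @param g A [gene_model()] with >= 2 transcripts.
#' @param genome Reference sequences.
#' @return Logical.
#' @export
encode_same_protein <- function(g, genome) {
  if (length(g$transcripts) < 2L) stop("needs >= 2 transcripts")
  cds <- vapply(g$transcripts, function(t) {
    if (is.na(t$cds_start)) NA_character_ else cds_sequence(t, genome)
  }, "")
  if (anyNA(cds)) return(FALSE)
  length(unique(cds)) == 1L
}

## the reference transcript: productive (not NMD-doomed) first, then
## best-supported, ties to the longest CDS then id
reference_transcript <- function(g, grades, genome, nmd_distance = 50L) {
  sc <- grades$n_independent[match(names(g$transcripts), grades$transcript_id)]
  sc[is.na(sc)] <- 0L
  tot <- grades$n_support[match(names(g$transcripts), grades$transcript_id)]
  tot[is.na(tot)] <- 0L
  cdslen <- vapply(g$transcripts, function(t) {
    if (is.na(t$cds_start)) 0L else nchar(cds_sequence(t, genome))
  }, 0L)
  productive <- vapply(g$transcripts, function(t) {
    if (is.na(t$cds_start)) return(FALSE)
    !isTRUE(assess_nmd(t, genome, nmd_distance)$is_ptc)
  }, TRUE)
  ord <- order(-productive, -sc, -tot, -cdslen, names(g$transcripts))
  names(g$transcripts)[ord[1L]]
}

#' Apply the discount rules to each alternative transcript
#'
#' Per alternative (non-reference) transcript the fired rules are collected:
#' * `BLOCKING_UORF` - the proposed 5' UTR contains an out-of-frame upstream
#'   ATG with no stop before the main start ([scan_uorfs()]);
#' * `WRONG_FRAME` - translation requires a different reading frame over the
#'   shared terminal exon ([compare_terminal_frames()]) and the transcript
#'   rests on a single support record;
#' * `UNSPLICED_PRIMARY` - the transcript's only support corresponds to the
#'   unspliced primary transcript;
#' * `NO_PRODUCTIVE_ALTERNATIVE` - the transcript's reading frame meets a
#'   premature termination codon and NMD would be expected to degrade it
#'   ([assess_nmd()]).
#'
#' @param g A [gene_model()].
#' @param genome Reference sequences.
#' @param grades Output of [grade_evidence()].
#' @param reference Reference transcript id (defaults to the best
#'   supported).
#' @param config A [classify_config()].
#' @return Named list: transcript id -> character vector of reasons (empty
#'   when no rule fires). The reference transcript is not assessed.
#' @export
apply_discount_rules <- function(g, genome, grades,
                                 reference = NULL,
                                 config = classify_config()) {
  if (is.null(reference)) reference <- reference_transcript(g, grades, genome)
  ref <- g$transcripts[[reference]]
  alts <- g$transcripts[names(g$transcripts) != reference]
  out <- stats::setNames(vector("list", length(alts)), names(alts))
  for (t in alts) {
    reasons <- character(0)
    if (!is.na(t$cds_start)) {
      u <- scan_uorfs(t, genome)
      if (nrow(u) > 0L && any(u$blocks_main)) reasons <- c(reasons, "BLOCKING_UORF")
      nmd <- assess_nmd(t, genome, config$nmd_distance)
      if (isTRUE(nmd$is_ptc)) reasons <- c(reasons, "NO_PRODUCTIVE_ALTERNATIVE")
      gr <- grades[grades$transcript_id == t$id, ]
      frame_off <- tryCatch(compare_terminal_frames(t, ref),
                            error = function(e) NA_integer_)
      if (!is.na(frame_off) && frame_off != 0L &&
          nrow(gr) == 1L && gr$n_support <= 1L)
        reasons <- c(reasons, "WRONG_FRAME")
      if (nrow(gr) == 1L && gr$n_support > 0L && isTRUE(gr$unspliced))
        reasons <- c(reasons, "UNSPLICED_PRIMARY")
    }
    out[[t$id]] <- reasons
  }
  out
}

grade_rank <- function(grade) match(grade, c("STRONG", "WEAK", "UNSUPPORTED"))

## weakest grade over a set of transcripts; UNSUPPORTED maps to WEAK at the
## category level (annotation without EST support is weak evidence)
category_grade <- function(tids, grades) {
  gr <- grades$grade[match(tids, grades$transcript_id)]
  gr[is.na(gr)] <- "UNSUPPORTED"
  if (all(gr == "STRONG")) "STRONG" else "WEAK"
}

mechanism_category <- function(mech, grade) {
  switch(mech,
         UNIQUE_START = paste0("UNIQUE_START_", grade),
         NESTED_START = "NESTED_START",  # no strong/weak split
         ALT_TERMINAL = paste0("ALT_TERMINAL_", grade),
         CASSETTE_EXON = paste0("CASSETTE_", grade),
         RETAINED_INTRON = paste0("RETAINED_INTRON_", grade),
         SPLICE_SHIFT = paste0("SPLICE_SHIFT_", grade))
}

#' Classify one gene
#'
#' Assignment proceeds in priority order: `NO_ALTERNATIVE` (a single
#' distinct transcript) -> `SAME_PROTEIN` (alternatives differing only in
#' untranslated regions) -> `DISCOUNTED` (every alternative removed by a
#' discount rule) -> a single-mechanism category whose strong/weak grade is
#' the minimum over the transcripts involved (`STRONG` only when every one
#' grades strong; nested starts carry no grade split) -> `MULTIPLE_STRONG` /
#' `MULTIPLE_WEAK` when two or more distinct mechanism types survive
#' discounting.
#'
#' @param g A [gene_model()].
#' @param genome Reference sequences.
#' @param records Support-record data.frame (may have zero rows).
#' @param config A [classify_config()].
#' @return An object of class `"ClassificationResult"`: list with `gene_id`,
#'   `category`, `mechanisms` (call data.frame), `grades`,
#'   `discount_reasons` (named list) and `warnings`.
#' @export
classify_gene <- function(g, genome, records = NULL,
                          config = classify_config()) {
  if (is.null(records)) records <- support_records(character(0), character(0),
                                                   character(0), character(0),
                                                   character(0), character(0))
  res <- function(category, mechanisms = empty_calls(), grades = NULL,
                  discount = list(), warnings = character(0)) {
    structure(list(gene_id = g$id, category = category,
                   mechanisms = mechanisms, grades = grades,
                   discount_reasons = discount, warnings = warnings),
              class = "ClassificationResult")
  }

  # distinct transcript structures (exon chain + CDS endpoints)
  sig <- vapply(g$transcripts, function(t)
    paste(c(t$exons, t$cds_start, t$cds_end), collapse = ","), "")
  if (length(unique(sig)) == 1L) return(res("NO_ALTERNATIVE"))

  if (encode_same_protein(g, genome)) return(res("SAME_PROTEIN"))

  calls <- detect_mechanisms(g, config$tolerance, config$min_overlap)
  assignment <- assign_support(records, g, config$tolerance)
  grades <- grade_evidence(assignment, g, config$strong_threshold)
  reference <- reference_transcript(g, grades, genome)
  discount <- apply_discount_rules(g, genome, grades, reference, config)

  discounted <- names(discount)[vapply(discount, length, 0L) > 0L]
  alive <- setdiff(names(g$transcripts), discounted)

  # drop calls whose alternative transcripts were all discounted
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    inv <- setdiff(stats::na.omit(c(calls$t1[i], calls$t2[i],
                                    calls$host[i])), reference)
    length(inv) == 0L || any(inv %in% alive)
  }, TRUE)
  calls_alive <- calls[keep, , drop = FALSE]

  if (length(setdiff(names(g$transcripts), c(reference, discounted))) == 0L ||
      nrow(calls_alive) == 0L) {
    if (length(unlist(discount)) == 0L)  # structural difference with no call
      discount <- lapply(discount, function(x) "NO_PRODUCTIVE_ALTERNATIVE")
    return(res("DISCOUNTED", calls, grades, discount))
  }

  types <- unique(calls_alive$mechanism)
  if (length(types) >= 2L) {
    inv <- setdiff(involved_transcripts(calls_alive), discounted)
    cat_ <- paste0("MULTIPLE_", category_grade(inv, grades))
    return(res(cat_, calls_alive, grades, discount))
  }
  mech <- types[1L]
  inv <- setdiff(involved_transcripts(calls_alive), discounted)
  res(mechanism_category(mech, category_grade(inv, grades)),
      calls_alive, grades, discount)
}

#' @export
print.ClassificationResult <- function(x, ...) {
  cat(sprintf("Gene %s: %s", x$gene_id, x$category))
  if (nrow(x$mechanisms))
    cat(sprintf(" [%s]", paste(unique(x$mechanisms$mechanism), collapse = "+")))
  disc <- unlist(x$discount_reasons)
  if (length(disc)) cat(sprintf(" (discounted: %s)",
                                paste(unique(disc), collapse = ",")))
  cat("\n")
  invisible(x)
}

#' Classify a cohort of genes
#'
#' @param genes Named list of [gene_model()]s.
#' @param genome Reference sequences.
#' @param records Support-record data.frame covering all genes.
#' @param config A [classify_config()].
#' @return data.frame with one row per gene: `gene_id`, `category`,
#'   `mechanisms` (comma-joined types), `discount_reasons` (comma-joined).
#' @export
classify_cohort <- function(genes, genome, records = NULL,
                            config = classify_config()) {
  rows <- lapply(genes, function(g) {
    r <- classify_gene(g, genome, records, config)
    data.frame(gene_id = r$gene_id, category = r$category,
               mechanisms = paste(unique(r$mechanisms$mechanism),
                                  collapse = ","),
               discount_reasons = paste(unique(unlist(r$discount_reasons)),
                                        collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene_id = character(0),
                                      category = character(0),
                                      mechanisms = character(0),
                                      discount_reasons = character(0))
  rownames(out) <- NULL
  out
}

#' Summarize a cohort of classifications into a category count table
#'
#' The categories partition the cohort: the counts always sum to the number
#' of genes.
#'
#' @param results data.frame from [classify_cohort()] (or anything with a
#'   `category` column).
#' @return data.frame `category` / `n` over the full category set, plus a
#'   `"TOTAL"` row.
#' @export
summarize_cohort <- function(results) {
  n <- vapply(CATEGORIES, function(cat_) sum(results$category == cat_), 0L)
  out <- data.frame(category = c(CATEGORIES, "TOTAL"),
                    n = c(n, nrow(results)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
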