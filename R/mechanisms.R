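# Structural detectors for the mechanisms that generate alternative
# transcripts, by pairwise exon-chain comparison:
#   UNIQUE_START    - alternative first exon unique to one transcript
#   NESTED_START    - shorter transcript starting inside an exon of a longer
#   ALT_TERMINAL    - alternative transcript end (exon extension or unique
#                     3' exon)
#   CASSETTE_EXON   - internal exon included in some transcripts, skipped in
#                     others
#   RETAINED_INTRON - intron spliced out of some transcripts, exonic in
#                     others
#   SPLICE_SHIFT    - alternative donor/acceptor selection at one junction
# All detectors work on genomic half-open intervals and are symmetric in
# transcript order and invariant under strand flip of the whole locus.

MECHANISMS <- c("UNIQUE_START", "NESTED_START", "ALT_TERMINAL",
                "CASSETTE_EXON", "RETAINED_INTRON", "SPLICE_SHIFT")

mechanism_call <- function(mechanism, t1, t2 = NA_character_,
                           host = NA_character_, acceptor_coincident = NA,
                           case = NA_character_, nmd_hint = NA,
                           retained_in = NA_character_,
                           intron_index = NA_integer_,
                           exon_index = NA_integer_,
                           skipped_in = NA_character_,
                           side = NA_character_, offset = NA_integer_,
                           frame_preserved = NA) {
  data.frame(mechanism = mechanism, t1 = t1, t2 = t2, host = host,
             acceptor_coincident = acceptor_coincident, case = case,
             nmd_hint = nmd_hint, retained_in = retained_in,
             intron_index = as.integer(intron_index),
             exon_index = as.integer(exon_index), skipped_in = skipped_in,
             side = side, offset = as.integer(offset),
             frame_preserved = frame_preserved, stringsAsFactors = FALSE)
}

empty_calls <- function() mechanism_call("x", "x")[0L, ]

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

## is `sub` a suffix of `full` (both matrices of introns in transcript order)?
is_junction_suffix <- function(sub, full, tolerance = 0L) {
  k <- nrow(sub); m <- nrow(full)
  if (k > m) return(FALSE)
  if (k == 0L) return(TRUE)
  tailf <- full[(m - k + 1L):m, , drop = FALSE]
  all(abs(tailf[, "start"] - sub[, "start"]) <= tolerance &
      abs(tailf[, "end"] - sub[, "end"]) <= tolerance)
}

is_junction_prefix <- function(sub, full, tolerance = 0L) {
  k <- nrow(sub); m <- nrow(full)
  if (k > m) return(FALSE)
  if (k == 0L) return(TRUE)
  headf <- full[seq_len(k), , drop = FALSE]
  all(abs(headf[, "start"] - sub[, "start"]) <= tolerance &
      abs(headf[, "end"] - sub[, "end"]) <= tolerance)
}

## is transcript s a nested truncation of t: s's 5' terminus lies inside an
## exon of t (and is not t's own start) and s's junctions are a suffix of t's
is_nested_in <- function(s, t, tolerance = 0L) {
  p <- tx_start(s)
  point_in_exons(t, p) && tx_start(t) != p &&
    is_junction_suffix(introns_of(s), introns_of(t), tolerance)
}

#' Detect alternative unique starting exons
#'
#' A transcript is called when its first exon overlaps no exon of any other
#' transcript of the gene by `min_overlap` bases or more, implying a
#' distinct promoter with its own starting exon. Uniqueness that arises
#' purely from nesting does not count: a transcript is not called against
#' transcripts nested within it (their truncated chains cannot share its
#' first exon), nor is a nested transcript itself called -- such genes are
#' the nested-starts class, not the unique-start class.
#'
#' @param g A [gene_model()] with at least two transcripts.
#' @param min_overlap Overlap (bases) with any other exon that disqualifies
#'   a first exon; default 1 (any overlap disqualifies).
#' @return A mechanism-call data.frame, one `UNIQUE_START` row per
#'   qualifying transcript.
#' @export
find_unique_starts <- function(g, min_overlap = 1L) {
  txs <- g$transcripts
  if (length(txs) < 2L) return(empty_calls())
  calls <- list()
  for (t in txs) {
    others <- txs[names(txs) != t$id]
    fe <- t$exons[1L, ]
    clash <- any(vapply(others, function(o) {
      any(interval_overlap(fe["start"], fe["end"],
                           o$exons[, "start"], o$exons[, "end"]) >= min_overlap)
    }, TRUE))
    nesting <- any(vapply(others, function(o) {
      is_nested_in(o, t) || is_nested_in(t, o)
    }, TRUE))
    if (!clash && !nesting)
      calls[[length(calls) + 1L]] <- mechanism_call("UNIQUE_START", t$id)
  }
  if (length(calls)) do.call(rbind, calls) else empty_calls()
}

#' Detect nested alternative transcript starts
#'
#' A transcript `s` is nested when its 5' terminus lies inside an exon of
#' another transcript `t` (and is not `t`'s own start) and `s`'s splice
#' junctions are a suffix of `t`'s, so that `s` looks like `t` begun from an
#' internal position. Of all qualifying hosts, the one whose 5' terminus is
#' most 5' is reported. Whether the nested start coincides with a splice
#' acceptor of the host (the trans-splice interpretation) is recorded in
#' `acceptor_coincident` but not acted upon.
#'
#' @param g A [gene_model()].
#' @param tolerance Junction-match tolerance in bases.
#' @return Mechanism-call data.frame of `NESTED_START` rows with the `host`
#'   transcript in the detail.
#' @export
find_nested_starts <- function(g, tolerance = 0L) {
  txs <- g$transcripts
  if (length(txs) < 2L) return(empty_calls())
  fiveprime_rank <- function(t) if (g$strand == "+") tx_start(t) else -tx_start(t)
  calls <- list()
  for (s in txs) {
    p <- tx_start(s)
    hosts <- Filter(function(t) t$id != s$id && is_nested_in(s, t, tolerance),
                    txs)
    if (length(hosts) == 0L) next
    host <- hosts[[which.min(vapply(hosts, fiveprime_rank, 0))]]
    # acceptor positions of the host: 5' boundaries of its non-first exons
    acc <- if (nrow(host$exons) > 1L) {
      ex <- host$exons[-1L, , drop = FALSE]
      if (g$strand == "+") ex[, "start"] else ex[, "end"] - 1L
    } else integer(0)
    calls[[length(calls) + 1L]] <- mechanism_call(
      "NESTED_START", s$id, host$id, host = host$id,
      acceptor_coincident = p %in% acc)
  }
  if (length(calls)) do.call(rbind, calls) else empty_calls()
}

#' Detect alternative terminal exons
#'
#' Two cases are called for a transcript `a` against a transcript `b`:
#' * `"extension"`: `a`'s final exon shares its 5' boundary with an internal
#'   exon of `b` and extends 3' into what is intron in `b` (a foreshortened
#'   transcript terminating in an extended internal exon). These calls carry
#'   `nmd_hint = TRUE` since the reading frame typically meets a stop well
#'   before `b`'s end.
#' * `"unique_exon"`: `a`'s final exon overlaps no exon of `b` and lies 3'
#'   of the junction chain shared with `b`.
#'
#' @param g A [gene_model()].
#' @param tolerance Junction-match tolerance in bases.
#' @return Mechanism-call data.frame of `ALT_TERMINAL` rows; `t1` is the
#'   alternatively terminated transcript, `case` records which case fired.
#' @export
find_alt_terminals <- function(g, tolerance = 0L) {
  txs <- g$transcripts
  if (length(txs) < 2L) return(empty_calls())
  plus <- g$strand == "+"
  calls <- list()
  for (a in txs) for (b in txs) {
    if (a$id == b$id) next
    na <- nrow(a$exons); nb <- nrow(b$exons)
    la <- a$exons[na, ]
    ia <- introns_of(a); ib <- introns_of(b)
    # case (a): extension of an internal exon of b into b's intron
    ext <- FALSE
    for (j in seq_len(nb)) {
      if (j == 1L || j == nb) next  # internal exons of b only
      eb <- b$exons[j, ]
      same_5p <- if (plus) la["start"] == eb["start"] else la["end"] == eb["end"]
      beyond_3p <- if (plus) la["end"] > eb["end"] else la["start"] < eb["start"]
      if (!(same_5p && beyond_3p)) next
      nxt <- b$exons[j + 1L, ]  # 3' end must stay within b's following intron
      within <- if (plus) la["end"] <= nxt["start"] else la["start"] >= nxt["end"]
      shared_chain <- is_junction_prefix(ia, ib, tolerance) &&
        nrow(ia) == j - 1L
      if (within && shared_chain) { ext <- TRUE; break }
    }
    if (ext) {
      calls[[length(calls) + 1L]] <- mechanism_call(
        "ALT_TERMINAL", a$id, b$id, case = "extension", nmd_hint = TRUE)
      next
    }
    # case (b): unique final exon 3' of the shared chain
    if (na >= 2L) {
      no_overlap <- !any(interval_overlap(la["start"], la["end"],
                                          b$exons[, "start"], b$exons[, "end"]) > 0L)
      shared_prefix <- nrow(ia) >= 1L &&
        is_junction_prefix(ia[-nrow(ia), , drop = FALSE], ib, tolerance)
      three_prime <- if (plus) la["start"] >= a$exons[na - 1L, "end"]
                     else la["end"] <= a$exons[na - 1L, "start"]
      if (no_overlap && shared_prefix && three_prime)
        calls[[length(calls) + 1L]] <- mechanism_call(
          "ALT_TERMINAL", a$id, b$id, case = "unique_exon", nmd_hint = FALSE)
    }
  }
  dedup_calls(calls)
}

#' Detect retained (non-constitutive) introns
#'
#' An intron of transcript `a` is called retained in transcript `b` when it
#' is fully exonic in `b` and the two transcripts are otherwise
#' junction-identical over their genomic overlap.
#'
#' @param g A [gene_model()].
#' @return Mechanism-call data.frame of `RETAINED_INTRON` rows; `t1` is the
#'   splicing transcript, `retained_in` the retaining one and `intron_index`
#'   the 1-based intron index in `t1` (transcript order).
#' @export
find_retained_introns <- function(g) {
  txs <- g$transcripts
  if (length(txs) < 2L) return(empty_calls())
  calls <- list()
  for (a in txs) for (b in txs) {
    if (a$id == b$id) next
    ia <- introns_of(a); ib <- introns_of(b)
    if (nrow(ia) == 0L) next
    region <- c(max(min(a$exons[, "start"]), min(b$exons[, "start"])),
                min(max(a$exons[, "end"]), max(b$exons[, "end"])))
    inside <- function(m) m[m[, "start"] >= region[1L] &
                            m[, "end"] <= region[2L], , drop = FALSE]
    for (i in seq_len(nrow(ia))) {
      intr <- ia[i, ]
      exonic_in_b <- any(b$exons[, "start"] <= intr["start"] &
                         intr["end"] <= b$exons[, "end"])
      if (!exonic_in_b) next
      rest_a <- junction_signature(inside(ia[-i, , drop = FALSE]))
      all_b <- junction_signature(inside(ib))
      if (identical(sort(rest_a), sort(all_b)))
        calls[[length(calls) + 1L]] <- mechanism_call(
          "RETAINED_INTRON", a$id, b$id, retained_in = b$id, intron_index = i)
    }
  }
  dedup_calls(calls)
}

#' Detect cassette (non-constitutive) internal exons
#'
#' An internal exon of transcript `a` is called a cassette exon when it lies
#' wholly within a single intron of transcript `b` whose boundaries coincide
#' with `a`'s flanking junctions (so that `a` and `b` share the donor and
#' acceptor flanking the optional exon).
#'
#' @param g A [gene_model()].
#' @return Mechanism-call data.frame of `CASSETTE_EXON` rows; `t1` is the
#'   including transcript, `skipped_in` the skipping one and `exon_index`
#'   the 1-based exon index in `t1` (transcript order).
#' @export
find_cassette_exons <- function(g) {
  txs <- g$transcripts
  if (length(txs) < 2L) return(empty_calls())
  calls <- list()
  for (a in txs) for (b in txs) {
    if (a$id == b$id) next
    na <- nrow(a$exons)
    if (na < 3L) next
    ia <- introns_of(a); ib <- introns_of(b)
    if (nrow(ib) == 0L) next
    for (i in 2L:(na - 1L)) {
      e <- a$exons[i, ]
      up <- ia[i - 1L, ]; down <- ia[i, ]
      merged <- c(start = min(up["start"], down["start"]),
                  end = max(up["end"], down["end"]))
      hit <- which(ib[, "start"] == merged["start"] &
                   ib[, "end"] == merged["end"])
      if (length(hit) && e["start"] >= merged["start"] &&
          e["end"] <= merged["end"])
        calls[[length(calls) + 1L]] <- mechanism_call(
          "CASSETTE_EXON", a$id, b$id, skipped_in = b$id, exon_index = i)
    }
  }
  dedup_calls(calls)
}

#' Detect splice-site shifts (alternative donor/acceptor selection)
#'
#' Called per junction where two transcripts use donors (or acceptors)
#' differing by some offset while the partner site of the junction matches.
#' Shifts that are a multiple of three bases preserve the translational
#' reading frame (`frame_preserved`).
#'
#' @param g A [gene_model()].
#' @return Mechanism-call data.frame of `SPLICE_SHIFT` rows with `side`
#'   (`"donor"` or `"acceptor"`), `offset` (bases, > 0) and
#'   `frame_preserved` in the detail.
#' @export
find_splice_shifts <- function(g) {
  txs <- g$transcripts
  if (length(txs) < 2L) return(empty_calls())
  plus <- g$strand == "+"
  ids <- names(txs)
  calls <- list()
  for (x in seq_along(txs)) for (y in seq_along(txs)) {
    if (x >= y) next
    a <- txs[[x]]; b <- txs[[y]]
    ia <- introns_of(a); ib <- introns_of(b)
    if (nrow(ia) == 0L || nrow(ib) == 0L) next
    # the region between the two alternative sites must contain no complete
    # exon of either transcript, else the difference is a cassette exon or
    # an alternative first/terminal exon, not a site shift
    exon_free <- function(lo, hi) {
      exs <- rbind(a$exons, b$exons)
      !any(exs[, "start"] >= lo & exs[, "end"] <= hi)
    }
    for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
      s1 <- ia[i, "start"]; e1 <- ia[i, "end"]
      s2 <- ib[j, "start"]; e2 <- ib[j, "end"]
      if (s1 == s2 && e1 != e2 && exon_free(min(e1, e2), max(e1, e2))) {
        d <- abs(e1 - e2)
        side <- if (plus) "acceptor" else "donor"
        calls[[length(calls) + 1L]] <- mechanism_call(
          "SPLICE_SHIFT", a$id, b$id, side = side, offset = d,
          frame_preserved = d %% 3L == 0L)
      } else if (e1 == e2 && s1 != s2 && exon_free(min(s1, s2), max(s1, s2))) {
        d <- abs(s1 - s2)
        side <- if (plus) "donor" else "acceptor"
        calls[[length(calls) + 1L]] <- mechanism_call(
          "SPLICE_SHIFT", a$id, b$id, side = side, offset = d,
          frame_preserved = d %% 3L == 0L)
      }
    }
  }
  dedup_calls(calls)
}

dedup_calls <- function(calls) {
  if (length(calls) == 0L) return(empty_calls())
  df <- do.call(rbind, calls)
  # symmetric dedup: a call and its transcript-swapped twin are one event
  key <- apply(df, 1L, function(r) {
    pair <- sort(c(r[["t1"]], r[["t2"]]))
    paste(c(r[["mechanism"]], pair, r[["case"]], r[["retained_in"]],
            r[["intron_index"]], r[["exon_index"]], r[["skipped_in"]],
            r[["side"]], r[["offset"]]), collapse = "|")
  })
  df[!duplicated(key), , drop = FALSE]
}

#' Run all mechanism detectors on a gene
#'
#' @param g A [gene_model()].
#' @param tolerance Junction-match tolerance in bases.
#' @param min_overlap Disqualifying overlap for [find_unique_starts()].
#' @return Combined mechanism-call data.frame (zero rows when nothing is
#'   detected).
#' @export
detect_mechanisms <- function(g, tolerance = 0L, min_overlap = 1L) {
  out <- rbind(find_unique_starts(g, min_overlap),
               find_nested_starts(g, tolerance),
               find_alt_terminals(g, tolerance),
               find_retained_introns(g),
               find_cassette_exons(g),
               find_splice_shifts(g))
  rownames(out) <- NULL
  out
}

#' Transcripts involved in a set of mechanism calls
#' @param calls A mechanism-call data.frame.
#' @return Character vector of transcript ids.
#' @export
involved_transcripts <- function(calls) {
  unique(stats::na.omit(c(calls$t1, calls$t2)))
}
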