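# Independent brute-force oracles: every routine here works base-by-base on
# enumerated coordinate sets (or single-codon loops), deliberately avoiding
# the interval arithmetic of the implementation it checks.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

## spliced sequence by walking exon bases one at a time
oracle_spliced_sequence <- function(t, genome_seq) {
  out <- character(0)
  for (i in seq_len(nrow(t$exons))) {
    s <- t$exons[i, "start"]; e <- t$exons[i, "end"]
    if (t$strand == "+") {
      for (p in s:(e - 1L)) out <- c(out, substring(genome_seq, p + 1L, p + 1L))
    } else {
      for (p in (e - 1L):s)
        out <- c(out, COMP[[substring(genome_seq, p + 1L, p + 1L)]])
    }
  }
  paste(out, collapse = "")
}

## codon-by-codon translation loop
oracle_translate <- function(seq, off) {
  i <- off
  n_aa <- 0L
  repeat {
    codon <- substring(seq, i + 1L, i + 3L)
    if (nchar(codon) < 3L)
      return(list(protein_length = n_aa, stop_offset = NA_integer_,
                  runs_off_end = TRUE))
    if (codon %in% c("TAA", "TAG", "TGA"))
      return(list(protein_length = n_aa, stop_offset = i,
                  runs_off_end = FALSE))
    n_aa <- n_aa + 1L
    i <- i + 3L
  }
}

## ---- base-set helpers -------------------------------------------------

iv_bases <- function(s, e) if (e > s) seq.int(s, e - 1L) else integer(0)
exon_bases <- function(t) {
  unlist(lapply(seq_len(nrow(t$exons)), function(i)
    iv_bases(t$exons[i, "start"], t$exons[i, "end"])))
}
asc_exons <- function(t) t$exons[order(t$exons[, "start"]), , drop = FALSE]
## junctions as "end:start" strings from ascending-sorted exons
junc_strings <- function(t) {
  ex <- asc_exons(t)
  n <- nrow(ex)
  if (n < 2L) return(character(0))
  paste(ex[-n, "end"], ex[-1L, "start"], sep = ":")
}
## reading-order first base
first_base <- function(t) {
  b <- exon_bases(t)
  if (t$strand == "+") min(b) else max(b)
}

oracle_is_nested <- function(s, t) {
  p <- first_base(s)
  js <- junc_strings(s); jt <- junc_strings(t)
  suffix_ok <- length(js) <= length(jt) &&
    (length(js) == 0L ||
       identical(jt[(length(jt) - length(js) + 1L):length(jt)], js))
  if (t$strand == "-") {  # reading order suffix = ascending-order prefix
    suffix_ok <- length(js) <= length(jt) &&
      (length(js) == 0L || identical(jt[seq_along(js)], js))
  }
  (p %in% exon_bases(t)) && p != first_base(t) && suffix_ok
}

oracle_unique_starts <- function(g, min_overlap = 1L) {
  txs <- g$transcripts
  out <- character(0)
  for (t in txs) {
    fe <- iv_bases(t$exons[1L, "start"], t$exons[1L, "end"])
    others <- txs[names(txs) != t$id]
    clash <- FALSE; nesting <- FALSE
    for (o in others) {
      for (i in seq_len(nrow(o$exons))) {
        ob <- iv_bases(o$exons[i, "start"], o$exons[i, "end"])
        if (length(intersect(fe, ob)) >= min_overlap) clash <- TRUE
      }
      if (oracle_is_nested(o, t) || oracle_is_nested(t, o)) nesting <- TRUE
    }
    if (!clash && !nesting) out <- c(out, t$id)
  }
  sort(out)
}

## nested calls as "s<host" strings, host = qualifying t with most 5' start
oracle_nested_starts <- function(g) {
  txs <- g$transcripts
  out <- character(0)
  for (s in txs) {
    hosts <- Filter(function(t) t$id != s$id && oracle_is_nested(s, t), txs)
    if (length(hosts) == 0L) next
    fb <- vapply(hosts, first_base, 0L)
    host <- if (g$strand == "+") hosts[[which.min(fb)]]
            else hosts[[which.max(fb)]]
    out <- c(out, paste0(s$id, "<", host$id))
  }
  sort(out)
}

## retained introns as "a|b|i" (i = intron index in reading order of a)
oracle_retained_introns <- function(g) {
  txs <- g$transcripts
  out <- character(0)
  for (a in txs) for (b in txs) {
    if (a$id == b$id) next
    exa <- asc_exons(a)
    na <- nrow(exa)
    if (na < 2L) next
    eb <- exon_bases(b)
    lo <- max(min(exon_bases(a)), min(eb))
    hi <- min(max(exon_bases(a)) + 1L, max(eb) + 1L)
    in_region <- function(str) {
      p <- as.integer(strsplit(str, ":")[[1L]])
      p[1L] >= lo && p[2L] <= hi
    }
    ja <- junc_strings(a); jb <- junc_strings(b)
    for (k in seq_len(na - 1L)) {
      ib <- iv_bases(exa[k, "end"], exa[k + 1L, "start"])
      exonic <- all(ib %in% eb) &&
        any(vapply(seq_len(nrow(b$exons)), function(i)
          all(ib %in% iv_bases(b$exons[i, "start"], b$exons[i, "end"])), TRUE))
      if (!exonic) next
      resta <- sort(Filter(in_region, ja[-k]))
      allb <- sort(Filter(in_region, jb))
      if (identical(resta, allb)) {
        idx <- if (a$strand == "+") k else na - k  # reading-order index
        out <- c(out, paste(a$id, b$id, idx, sep = "|"))
      }
    }
  }
  sort(unique(out))
}

## cassette exons as "a|b|i" (i = exon index in reading order of a)
oracle_cassette_exons <- function(g) {
  txs <- g$transcripts
  out <- character(0)
  for (a in txs) for (b in txs) {
    if (a$id == b$id) next
    exa <- asc_exons(a); exb <- asc_exons(b)
    na <- nrow(exa); nb <- nrow(exb)
    if (na < 3L || nb < 2L) next
    for (k in 2L:(na - 1L)) {
      e <- iv_bases(exa[k, "start"], exa[k, "end"])
      for (j in seq_len(nb - 1L)) {
        intr <- iv_bases(exb[j, "end"], exb[j + 1L, "start"])
        if (all(e %in% intr) &&
            exb[j, "end"] == exa[k - 1L, "end"] &&
            exb[j + 1L, "start"] == exa[k + 1L, "start"]) {
          idx <- if (a$strand == "+") k else na - k + 1L
          out <- c(out, paste(a$id, b$id, idx, sep = "|"))
        }
      }
    }
  }
  sort(unique(out))
}

## alternative terminal exons as "a|b|case" (plus-strand toys)
oracle_alt_terminals <- function(g) {
  txs <- g$transcripts
  out <- character(0)
  for (a in txs) for (b in txs) {
    if (a$id == b$id) next
    exa <- asc_exons(a); exb <- asc_exons(b)
    na <- nrow(exa); nb <- nrow(exb)
    la <- exa[na, ]
    ja <- junc_strings(a); jb <- junc_strings(b)
    hit <- NULL
    for (j in seq_len(nb)) {
      if (j == 1L || j == nb) next
      if (la["start"] == exb[j, "start"] && la["end"] > exb[j, "end"] &&
          la["end"] <= exb[j + 1L, "start"] &&
          length(ja) == j - 1L && identical(ja, jb[seq_len(j - 1L)])) {
        hit <- "extension"; break
      }
    }
    if (is.null(hit) && na >= 2L) {
      lb_bases <- iv_bases(la["start"], la["end"])
      no_ov <- length(intersect(lb_bases, exon_bases(b))) == 0L
      prefix <- length(ja) >= 1L &&
        (length(ja) == 1L ||
           identical(ja[seq_len(length(ja) - 1L)],
                     jb[seq_len(length(ja) - 1L)])) &&
        length(ja) - 1L <= length(jb)
      three_p <- la["start"] >= exa[na - 1L, "end"]
      if (no_ov && prefix && three_p) hit <- "unique_exon"
    }
    if (!is.null(hit)) out <- c(out, paste(a$id, b$id, hit, sep = "|"))
  }
  sort(unique(out))
}

## splice shifts as "t1|t2|side|offset" with pair sorted
oracle_splice_shifts <- function(g) {
  txs <- g$transcripts
  out <- character(0)
  ids <- names(txs)
  plus <- g$strand == "+"
  for (x in seq_along(txs)) for (y in seq_along(txs)) {
    if (x >= y) next
    a <- txs[[x]]; b <- txs[[y]]
    exa <- asc_exons(a); exb <- asc_exons(b)
    allex <- rbind(exa, exb)
    exon_inside <- function(lo, hi) {
      any(vapply(seq_len(nrow(allex)), function(i)
        all(iv_bases(allex[i, "start"], allex[i, "end"]) %in%
              iv_bases(lo, hi)) && allex[i, "end"] > allex[i, "start"], TRUE))
    }
    for (i in seq_len(nrow(exa) - 1L)) for (j in seq_len(nrow(exb) - 1L)) {
      s1 <- exa[i, "end"]; e1 <- exa[i + 1L, "start"]
      s2 <- exb[j, "end"]; e2 <- exb[j + 1L, "start"]
      if (s1 == s2 && e1 != e2 && !exon_inside(min(e1, e2), max(e1, e2)))
        out <- c(out, paste(a$id, b$id, if (plus) "acceptor" else "donor",
                            abs(e1 - e2), sep = "|"))
      if (e1 == e2 && s1 != s2 && !exon_inside(min(s1, s2), max(s1, s2)))
        out <- c(out, paste(a$id, b$id, if (plus) "donor" else "acceptor",
                            abs(s1 - s2), sep = "|"))
    }
  }
  sort(unique(out))
}

## reporter expression oracle: rebuild the spliced sequence base-by-base and
## walk codons from the annotated start; expressed iff every reporter base
## is covered by a codon read in frame 0 before any stop
oracle_reporter_expresses <- function(t, genome_seq, reporter_span) {
  if (is.na(t$cds_start)) return(FALSE)
  rep_bases <- iv_bases(reporter_span[[1L]], reporter_span[[2L]])
  # genomic base per spliced position, in reading order
  gpos <- integer(0)
  for (i in seq_len(nrow(t$exons))) {
    s <- t$exons[i, "start"]; e <- t$exons[i, "end"]
    gpos <- c(gpos, if (t$strand == "+") s:(e - 1L) else (e - 1L):s)
  }
  if (!all(rep_bases %in% gpos)) return(FALSE)
  seq <- oracle_spliced_sequence(t, genome_seq)
  co <- which(gpos == t$cds_start) - 1L
  if (length(co) != 1L) return(FALSE)
  rb_first <- if (t$strand == "+") reporter_span[[1L]]
              else reporter_span[[2L]] - 1L
  covered <- logical(length(rep_bases))
  aligned <- FALSE
  i <- co
  repeat {
    codon <- substring(seq, i + 1L, i + 3L)
    if (nchar(codon) < 3L || codon %in% c("TAA", "TAG", "TGA")) break
    if (gpos[i + 1L] == rb_first) aligned <- TRUE  # codon starts the reporter
    for (k in 0:2) {
      idx <- match(gpos[i + k + 1L], rep_bases)
      if (!is.na(idx)) covered[idx] <- TRUE
    }
    i <- i + 3L
  }
  aligned && all(covered) && length(covered) > 0L
}
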