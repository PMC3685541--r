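# Toy builders: hand-coordinate transcripts and random exon-chain pairs
# used for detector-oracle comparisons.

## transcript from an ascending exon matrix; rows are reordered for minus
mk_tx <- function(id, exons_asc, strand = "+", chrom = "chr",
                  cds_start = NA, cds_end = NA) {
  ex <- exons_asc[order(exons_asc[, 1L], decreasing = (strand == "-")), ,
                  drop = FALSE]
  colnames(ex) <- c("start", "end")
  transcript(id, chrom, strand, ex, cds_start, cds_end)
}

mk_gene <- function(id, ...) gene_model(id, list(...))

## random ascending exon chain
random_chain <- function(n_ex = NULL, origin = NULL) {
  if (is.null(n_ex)) n_ex <- sample(3:6, 1L)
  if (is.null(origin)) origin <- sample(50:200, 1L)
  pos <- origin
  rows <- matrix(0L, n_ex, 2L)
  for (i in seq_len(n_ex)) {
    len <- sample(20:120, 1L)
    rows[i, ] <- c(pos, pos + len)
    pos <- pos + len + sample(30:90, 1L)
  }
  colnames(rows) <- c("start", "end")
  rows
}

## a second chain derived from `a` by a random structural change (or an
## unrelated chain), producing the variety the detectors must face
mutate_chain <- function(a) {
  n <- nrow(a)
  type <- sample(c("identical", "indep", "drop_exon", "merge_intron",
                   "shift_acceptor", "shift_donor", "truncate",
                   "new_first", "extend_terminal"), 1L)
  b <- a
  if (type == "identical") return(a)
  if (type == "indep") return(random_chain(origin = a[1L, 1L] + sample(-40:40, 1L)))
  if (type == "drop_exon" && n >= 3L) return(a[-sample(2:(n - 1L), 1L), , drop = FALSE])
  if (type == "merge_intron" && n >= 2L) {
    i <- sample(n - 1L, 1L)
    b <- a[-(i + 1L), , drop = FALSE]
    b[i, 2L] <- a[i + 1L, 2L]
    return(b)
  }
  if (type == "shift_acceptor" && n >= 2L) {
    i <- sample(2:n, 1L)
    d <- sample(1:12, 1L)
    if (a[i, 1L] + d < a[i, 2L]) b[i, 1L] <- a[i, 1L] + d
    return(b)
  }
  if (type == "shift_donor" && n >= 2L) {
    i <- sample(seq_len(n - 1L), 1L)
    d <- sample(1:12, 1L)
    if (a[i, 2L] - d > a[i, 1L]) b[i, 2L] <- a[i, 2L] - d
    return(b)
  }
  if (type == "truncate" && n >= 2L) {
    j <- sample(2:n, 1L)
    b <- a[j:n, , drop = FALSE]
    cut <- sample(0:(b[1L, 2L] - b[1L, 1L] - 10L), 1L)
    b[1L, 1L] <- b[1L, 1L] + max(0L, cut)
    return(b)
  }
  if (type == "new_first" && a[1L, 1L] > 60L) {
    len <- sample(15:min(50L, a[1L, 1L] - 10L), 1L)
    s <- sample(0:(a[1L, 1L] - len - 5L), 1L)
    return(rbind(c(s, s + len), a[-1L, , drop = FALSE]))
  }
  if (type == "extend_terminal" && n >= 3L) {
    j <- sample(2:(n - 1L), 1L)
    gap <- a[j + 1L, 1L] - a[j, 2L]
    b <- a[seq_len(j), , drop = FALSE]
    b[j, 2L] <- a[j, 2L] + sample(5:max(6L, gap - 5L), 1L)
    b[j, 2L] <- min(b[j, 2L], a[j + 1L, 1L])
    return(b)
  }
  a
}

random_toy_gene <- function(seed, strand = "+") {
  set.seed(seed)
  a <- random_chain()
  b <- mutate_chain(a)
  g <- gene_model("toy", list(mk_tx("tA", a, strand), mk_tx("tB", b, strand)))
  g
}

## summarize a call data.frame into comparable strings per mechanism
call_keys <- function(calls) {
  list(
    unique_start = sort(calls$t1[calls$mechanism == "UNIQUE_START"]),
    nested = sort(with(calls[calls$mechanism == "NESTED_START", ],
                       paste(t1, host, sep = "<"))),
    retained = sort(unique(with(calls[calls$mechanism == "RETAINED_INTRON", ],
                                paste(t1, retained_in, intron_index, sep = "|")))),
    cassette = sort(unique(with(calls[calls$mechanism == "CASSETTE_EXON", ],
                                paste(t1, skipped_in, exon_index, sep = "|")))),
    altterm = sort(unique(with(calls[calls$mechanism == "ALT_TERMINAL", ],
                               paste(t1, t2, case, sep = "|")))),
    shift = sort(unique(with(calls[calls$mechanism == "SPLICE_SHIFT", ],
                             paste(t1, t2, side, offset, sep = "|"))))
  )
}

## apply edits to a generated locus and predict in one step
predict_reporter_with <- function(out, edits) {
  ed <- suppressWarnings(apply_edits(out$gene, out$genome, edits))
  predict_reporter(ed$gene, ed$genome, ed$reporter_span)
}

## random synthetic gene + one random edit set for reporter-oracle checks
random_reporter_case <- function(seed) {
  set.seed(seed)
  mech <- sample(c("UNIQUE_START", "NESTED_START", "CASSETTE_EXON",
                   "RETAINED_INTRON", "SPLICE_SHIFT", "NONE"), 1L)
  out <- generate_gene(synthetic_gene_spec(
    mechanism = mech, id = "rg", seed = sample.int(1e6, 1L),
    strand = sample(c("+", "-"), 1L)))
  g <- out$gene
  txs <- g$transcripts
  t <- txs[[sample(length(txs), 1L)]]
  plus <- g$strand == "+"
  payload <- default_reporter_payload()
  where <- sample(c("after_start", "before_stop", "random_exonic",
                    "intronic"), 1L)
  pos <- switch(where,
    after_start = if (plus) t$cds_start + 3L else t$cds_start - 2L,
    before_stop = if (plus) t$cds_end - 2L else t$cds_end + 3L,
    random_exonic = {
      i <- sample(nrow(t$exons), 1L)
      sample((t$exons[i, "start"] + 1L):(t$exons[i, "end"] - 1L), 1L)
    },
    intronic = {
      intr <- introns_of(t)
      if (nrow(intr) == 0L) t$cds_start + 3L
      else {
        i <- sample(nrow(intr), 1L)
        sample((intr[i, "start"] + 3L):(intr[i, "end"] - 3L), 1L)
      }
    })
  edits <- list(edit_op("REPORTER_INSERTION", pos,
                        if (plus) payload else revcomp(payload)))
  if (sample(c(TRUE, FALSE), 1L)) {
    span <- g$span
    fs_pos <- sample((span["start"] + 3L):(span["end"] - 3L), 1L)
    fp <- vapply(edits, function(e) e$position, 0L)
    if (!fs_pos %in% fp)
      edits <- c(edits, list(edit_op("NT_INSERTION", fs_pos,
                                     sample(c("A", "C", "G", "T"), 1L))))
  }
  list(gene = g, genome = out$genome, edits = edits)
}
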