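# Synthetic locus generator: genomes, multi-transcript gene models realizing
# each alternative-transcript mechanism, and transcript-support evidence with
# realistic artifact modes (5'-truncated cDNAs from incomplete first-strand
# synthesis, unspliced genomic-span reads), so every pipeline stage can be
# exercised without external data.
#
# Construction notes: exon/intron boundaries are placed on codon boundaries
# and optional elements (cassette exons, retainable introns, terminal-exon
# extensions) are built from stop-free sense codons, so a planted mechanism
# is guaranteed productive unless the spec asks for a frame-shifting
# variant. Introns are canonical GT..AG. 5' UTRs are generated ATG-free so
# that no spurious upstream-ORF discounts fire on clean genes.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

SYNTH_MECHANISMS <- c("NONE", "SAME_PROTEIN", "UNIQUE_START", "NESTED_START",
                      "ALT_TERMINAL", "CASSETTE_EXON", "RETAINED_INTRON",
                      "SPLICE_SHIFT", "MULTIPLE")

## sample one element of x (safe for length-1 vectors)
pick1 <- function(x) x[sample.int(length(x), 1L)]

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random DNA guaranteed free of ATG (used for 5' UTRs)
rand_dna_no_atg <- function(n) {
  s <- rand_dna(n)
  while (grepl("ATG", s, fixed = TRUE))
    s <- sub("ATG", "ACG", s, fixed = TRUE)
  s
}

rand_codons <- function(k) {
  if (k <= 0L) return("")
  paste(sample(SENSE_CODONS, k, replace = TRUE), collapse = "")
}

make_intron <- function(len) {
  stopifnot(len >= 6L)
  paste0("GT", rand_dna(len - 4L), "AG")
}

## codon-structured intron: length 3m, starts GT (first codon GTN, valine),
## ends CAG, interior stop-free -- safe to retain in frame
make_retainable_intron <- function(m) {
  stopifnot(m >= 3L)
  paste0("GT", sample(c("A", "C", "G", "T"), 1L), rand_codons(m - 2L), "CAG")
}

#' Parameters for one synthetic gene locus
#'
#' Defaults describe a compact, well-expressed locus: 4-6 exons of 90-240
#' bases, introns of 48-150 bases, canonical GT..AG splice sites, an
#' ATG-free 5' UTR, 500 bases of flanking padding (so homology-arm
#' extraction always succeeds) and artifact-free evidence.
#'
#' @param mechanism One of `"NONE"`, `"SAME_PROTEIN"`, `"UNIQUE_START"`,
#'   `"NESTED_START"`, `"ALT_TERMINAL"`, `"CASSETTE_EXON"`,
#'   `"RETAINED_INTRON"`, `"SPLICE_SHIFT"`, `"MULTIPLE"`.
#' @param n_transcripts Number of alternative starts for `"UNIQUE_START"`
#'   (>= 2); other mechanisms determine their own transcript count.
#' @param exon_count_range,exon_length_range,intron_length_range Structural
#'   ranges (bases).
#' @param cassette_frame_preserving When `FALSE` the cassette exon length is
#'   1 mod 3, planting a frame-shift (and typically a premature stop) in the
#'   including transcript.
#' @param splice_shift_offsets Candidate donor/acceptor offsets (bases); the
#'   default in-frame offsets 3/6/9/12 reflect the shifts seen among
#'   annotated, NMD-surviving transcripts.
#' @param expression_weights Per-transcript sampling weights for evidence
#'   generation (default uniform).
#' @param p_truncated_5p,p_unspliced Artifact rates for [generate_ests()].
#' @param strand `"+"` or `"-"` (a minus-strand locus is the mirrored,
#'   reverse-complemented plus-strand construction).
#' @param pad Flanking padding (bases).
#' @param id Gene identifier.
#' @param seed Integer seed; the same spec yields a byte-identical locus.
#' @return A list of class `"SyntheticGeneSpec"`.
#' @export
synthetic_gene_spec <- function(mechanism = "NONE", n_transcripts = 2L,
                                exon_count_range = c(4L, 6L),
                                exon_length_range = c(90L, 240L),
                                intron_length_range = c(48L, 150L),
                                cassette_frame_preserving = TRUE,
                                splice_shift_offsets = c(3L, 6L, 9L, 12L),
                                expression_weights = NULL,
                                p_truncated_5p = 0, p_unspliced = 0,
                                strand = "+", pad = 500L,
                                id = "synth1", seed = 1L) {
  mechanism <- match.arg(mechanism, SYNTH_MECHANISMS)
  stopifnot(n_transcripts >= 2L, p_truncated_5p >= 0, p_truncated_5p <= 1,
            p_unspliced >= 0, p_unspliced <= 1, strand %in% c("+", "-"),
            pad >= 100L)
  structure(list(mechanism = mechanism, n_transcripts = as.integer(n_transcripts),
                 exon_count_range = as.integer(exon_count_range),
                 exon_length_range = as.integer(exon_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 cassette_frame_preserving = isTRUE(cassette_frame_preserving),
                 splice_shift_offsets = as.integer(splice_shift_offsets),
                 expression_weights = expression_weights,
                 p_truncated_5p = p_truncated_5p, p_unspliced = p_unspliced,
                 strand = strand, pad = as.integer(pad),
                 id = id, seed = as.integer(seed)),
            class = "SyntheticGeneSpec")
}

## mirror a gene model onto the opposite strand of a sequence of length L
mirror_point <- function(p, L) L - 1L - p

#' Mirror a gene model to the opposite strand
#'
#' Maps every coordinate x to L - x so the locus reads identically from the
#' other strand of the reverse-complemented sequence; used together with
#' [revcomp()] on the genome.
#'
#' @param g A [gene_model()].
#' @param L Length of the reference sequence.
#' @return The mirrored [gene_model()].
#' @export
mirror_gene_model <- function(g, L) {
  txs <- lapply(g$transcripts, function(t) {
    ex <- cbind(start = L - t$exons[, "end"], end = L - t$exons[, "start"])
    transcript(t$id, t$chrom, if (t$strand == "+") "-" else "+", ex,
               if (is.na(t$cds_start)) NA_integer_
               else mirror_point(t$cds_start, L),
               if (is.na(t$cds_end)) NA_integer_
               else mirror_point(t$cds_end, L),
               t$trans_spliced)
  })
  gene_model(g$id, txs, g$molecular_name, g$genetic_name)
}

expected_category_for <- function(mechanism, frame_preserving = TRUE) {
  switch(mechanism,
         NONE = "NO_ALTERNATIVE",
         SAME_PROTEIN = "SAME_PROTEIN",
         UNIQUE_START = "UNIQUE_START_STRONG",
         NESTED_START = "NESTED_START",
         ALT_TERMINAL = "ALT_TERMINAL_STRONG",
         CASSETTE_EXON = if (frame_preserving) "CASSETTE_STRONG" else "DISCOUNTED",
         RETAINED_INTRON = "RETAINED_INTRON_STRONG",
         SPLICE_SHIFT = "SPLICE_SHIFT_STRONG",
         MULTIPLE = "MULTIPLE_STRONG")
}

#' Generate one synthetic gene locus
#'
#' Builds a reference sequence and a [gene_model()] structurally realizing
#' the spec's mechanism, together with a truth record stating what was
#' planted. Introns are canonical GT..AG; the CDS starts ATG, ends at a
#' stop, and contains no internal in-frame stop in any productive
#' transcript.
#'
#' @param spec A [synthetic_gene_spec()].
#' @return List with `gene` (the [gene_model()]), `genome` (named character
#'   vector with one reference sequence) and `truth` (list: `gene_id`,
#'   `mechanism`, `expected_category`, `detail`).
#' @export
generate_gene <- function(spec) {
  set.seed(spec$seed)
  mech <- spec$mechanism
  chrom <- paste0(spec$id, "_ref")

  n_ex <- sample(seq(spec$exon_count_range[1L], spec$exon_count_range[2L]), 1L)
  m <- sample(seq(max(4L, spec$exon_length_range[1L] %/% 3L),
                  spec$exon_length_range[2L] %/% 3L), n_ex, replace = TRUE)
  utr5 <- rand_dna_no_atg(sample(15:45, 1L))
  utr3 <- rand_dna(sample(30:60, 1L))
  intron_lens <- sample(seq(spec$intron_length_range[1L],
                            spec$intron_length_range[2L]),
                        n_ex - 1L, replace = TRUE)

  cds_parts <- c(paste0("ATG", rand_codons(m[1L] - 1L)),
                 if (n_ex > 2L) vapply(m[2:(n_ex - 1L)], rand_codons, ""),
                 paste0(rand_codons(m[n_ex] - 1L), "TAA"))
  exon_seqs <- cds_parts
  exon_seqs[1L] <- paste0(utr5, cds_parts[1L])
  exon_seqs[n_ex] <- paste0(cds_parts[n_ex], utr3)
  intron_seqs <- vapply(intron_lens, make_intron, "")

  detail <- list()
  truth_mech <- mech

  ## mechanism-specific sequence surgery on the base structure ------------
  if (mech == "SPLICE_SHIFT") {
    i <- pick1(seq_len(n_ex - 1L)[-1L])  # junction into an internal/last exon
    d <- pick1(spec$splice_shift_offsets)
    # the codon ending at offset d of exon i+1 becomes CAG so the shifted
    # intron still ends in AG
    s <- exon_seqs[i + 1L]
    exon_seqs[i + 1L] <- paste0(substring(s, 1L, d - 3L), "CAG",
                                substring(s, d + 1L))
    detail <- list(junction = i, offset = d, side = "acceptor")
  }
  if (mech == "RETAINED_INTRON") {
    i <- pick1(seq_len(n_ex - 1L)[-1L])
    mi <- max(16L, intron_lens[i] %/% 3L)
    intron_seqs[i] <- make_retainable_intron(mi)
    detail <- list(intron_index = i)
  }
  cassette_seq <- NULL
  if (mech %in% c("CASSETTE_EXON", "MULTIPLE")) {
    # cassette sits in intron ci; a frame-shifting cassette is kept away
    # from the final intron so its premature stop stays > 50 nt upstream of
    # the last junction and NMD candidacy is unambiguous
    ci_pool <- if (spec$cassette_frame_preserving || mech == "MULTIPLE")
      seq_len(n_ex - 1L)[-1L] else seq_len(n_ex - 2L)[-1L]
    ci <- pick1(ci_pool)
    mc <- sample(12:30, 1L)
    # non-frame-preserving: length 1 mod 3 and an in-frame stop inside the
    # exon, so the including transcript is reliably PTC/NMD-doomed
    cassette_seq <- if (spec$cassette_frame_preserving || mech == "MULTIPLE")
      rand_codons(mc)
    else paste0(rand_codons(mc %/% 2L), "TAA",
                rand_dna(3L * (mc - mc %/% 2L - 1L) + 1L))
    detail$cassette_intron <- ci
  }
  ext_seq <- NULL
  if (mech == "ALT_TERMINAL") {
    j <- pick1(seq_len(n_ex - 1L)[-1L])  # T2 terminates in extended exon j
    we <- sample(4:8, 1L)
    ext_seq <- paste0("GT", sample(c("A", "C", "G", "T"), 1L),
                      rand_codons(we), "TAA", rand_dna(6L))
    need <- nchar(ext_seq) + 30L
    if (intron_lens[j] < need) intron_lens[j] <- need
    intron_seqs[j] <- paste0(ext_seq,
                             make_intron(intron_lens[j] - nchar(ext_seq)))
    intron_lens[j] <- nchar(intron_seqs[j])
    detail <- list(extended_exon = j, extension = nchar(ext_seq))
  }

  ## assemble the locus ---------------------------------------------------
  segs <- list(pad_l = rand_dna(spec$pad))
  alt_first <- list()  # id -> seg name of its first exon
  if (mech %in% c("UNIQUE_START", "MULTIPLE")) {
    k_alt <- if (mech == "UNIQUE_START") spec$n_transcripts - 1L else 1L
    for (k in rev(seq_len(k_alt))) {  # outermost alternative start first
      ma <- sample(10:20, 1L)
      nm <- paste0("altE1_", k)
      segs[[nm]] <- paste0(rand_dna_no_atg(sample(10:25, 1L)),
                           "ATG", rand_codons(ma - 1L))
      segs[[paste0("altsp_", k)]] <- paste0("GT", rand_dna(40L), "AG")
      alt_first[[nm]] <- nm
    }
  }
  if (mech == "SAME_PROTEIN") {
    segs[["utrE0"]] <- rand_dna_no_atg(sample(40:70, 1L))
    segs[["utrsp"]] <- paste0("GT", rand_dna(40L), "AG")
  }
  for (i in seq_len(n_ex)) {
    segs[[paste0("E", i)]] <- exon_seqs[i]
    if (i < n_ex) {
      if (!is.null(cassette_seq) && i == detail$cassette_intron) {
        half <- max(20L, intron_lens[i] %/% 2L)
        segs[[paste0("I", i, "a")]] <- make_intron(half)
        segs[[paste0("C")]] <- cassette_seq
        segs[[paste0("I", i, "b")]] <- make_intron(half)
      } else {
        segs[[paste0("I", i)]] <- intron_seqs[i]
      }
    }
  }
  segs[["pad_r"]] <- rand_dna(spec$pad)

  seqs <- unlist(segs)
  ends <- cumsum(nchar(seqs))
  starts <- stats::setNames(c(0L, ends[-length(ends)]), names(seqs))
  ends <- stats::setNames(as.integer(ends), names(seqs))
  genome_seq <- paste(seqs, collapse = "")
  L <- nchar(genome_seq)
  seg_iv <- function(nm) c(starts[[nm]], ends[[nm]])

  exon_iv <- function(i) {
    nm <- paste0("E", i)
    c(starts[[nm]], ends[[nm]])
  }
  base_exons <- t(vapply(seq_len(n_ex), exon_iv, integer(2L)))
  colnames(base_exons) <- c("start", "end")
  cds_start <- starts[["E1"]] + nchar(utr5)
  cds_end <- ends[[paste0("E", n_ex)]] - nchar(utr3) - 1L

  tx <- function(id, exons, cs = cds_start, ce = cds_end)
    transcript(id, chrom, "+", exons, cs, ce)

  txs <- list()
  t1_id <- paste0(spec$id, ".a")
  t2_id <- paste0(spec$id, ".b")
  t3_id <- paste0(spec$id, ".c")

  if (mech == "NONE") {
    txs[[t1_id]] <- tx(t1_id, base_exons)
  } else if (mech == "SAME_PROTEIN") {
    txs[[t1_id]] <- tx(t1_id, base_exons)
    ex2 <- rbind(seg_iv("utrE0"), base_exons)
    colnames(ex2) <- c("start", "end")
    txs[[t2_id]] <- tx(t2_id, ex2)
  } else if (mech == "UNIQUE_START") {
    txs[[t1_id]] <- tx(t1_id, base_exons)
    for (k in seq_len(spec$n_transcripts - 1L)) {
      nm <- paste0("altE1_", k)
      ex <- rbind(seg_iv(nm), base_exons[-1L, , drop = FALSE])
      colnames(ex) <- c("start", "end")
      utr_k <- regexpr("ATG", segs[[nm]], fixed = TRUE) - 1L
      id_k <- paste0(spec$id, ".", letters[k + 1L])
      txs[[id_k]] <- tx(id_k, ex, cs = starts[[nm]] + utr_k)
    }
  } else if (mech == "NESTED_START") {
    txs[[t1_id]] <- tx(t1_id, base_exons)
    j <- pick1(2:(n_ex - 1L))
    w <- max(2L, m[j] %/% 2L)
    q <- starts[[paste0("E", j)]] + 3L * (w - 1L)
    # plant an in-frame ATG at the nested start (Met substitution in t1)
    s <- segs[[paste0("E", j)]]
    off <- 3L * (w - 1L)
    segs[[paste0("E", j)]] <- paste0(substring(s, 1L, off), "ATG",
                                     substring(s, off + 4L))
    genome_seq <- paste(unlist(segs), collapse = "")
    ex2 <- rbind(c(q, ends[[paste0("E", j)]]),
                 base_exons[seq(j + 1L, n_ex), , drop = FALSE])
    colnames(ex2) <- c("start", "end")
    txs[[t2_id]] <- tx(t2_id, ex2, cs = q)
    detail <- list(host = t1_id, nested_exon = j)
  } else if (mech == "ALT_TERMINAL") {
    txs[[t1_id]] <- tx(t1_id, base_exons)
    j <- detail$extended_exon
    ex2 <- base_exons[seq_len(j), , drop = FALSE]
    ex2[j, "end"] <- ex2[j, "end"] + nchar(ext_seq)
    ce2 <- ends[[paste0("E", j)]] + nchar(ext_seq) - 6L - 1L  # last base of TAA
    txs[[t2_id]] <- tx(t2_id, ex2, ce = ce2)
  } else if (mech %in% c("CASSETTE_EXON", "MULTIPLE")) {
    ci <- detail$cassette_intron
    inc <- rbind(base_exons[seq_len(ci), , drop = FALSE],
                 seg_iv("C"),
                 base_exons[seq(ci + 1L, n_ex), , drop = FALSE])
    colnames(inc) <- c("start", "end")
    txs[[t1_id]] <- tx(t1_id, inc)       # includes the cassette exon
    txs[[t2_id]] <- tx(t2_id, base_exons)  # skips it
    detail$cassette_exon_index <- ci + 1L
    if (mech == "MULTIPLE") {
      nm <- "altE1_1"
      ex3 <- rbind(seg_iv(nm), base_exons[-1L, , drop = FALSE])
      colnames(ex3) <- c("start", "end")
      utr_k <- regexpr("ATG", segs[[nm]], fixed = TRUE) - 1L
      txs[[t3_id]] <- tx(t3_id, ex3, cs = starts[[nm]] + utr_k)
    }
  } else if (mech == "RETAINED_INTRON") {
    i <- detail$intron_index
    txs[[t1_id]] <- tx(t1_id, base_exons)  # splices the intron out
    ex2 <- rbind(base_exons[seq_len(i - 1L), , drop = FALSE],
                 c(base_exons[i, "start"], base_exons[i + 1L, "end"]),
                 if (i + 2L <= n_ex)
                   base_exons[seq(i + 2L, n_ex), , drop = FALSE])
    colnames(ex2) <- c("start", "end")
    txs[[t2_id]] <- tx(t2_id, ex2)         # retains it
  } else if (mech == "SPLICE_SHIFT") {
    i <- detail$junction; d <- detail$offset
    txs[[t1_id]] <- tx(t1_id, base_exons)
    ex2 <- base_exons
    ex2[i + 1L, "start"] <- ex2[i + 1L, "start"] + d
    txs[[t2_id]] <- tx(t2_id, ex2)
  }

  g <- gene_model(spec$id, txs, molecular_name = paste0(toupper(spec$id), ".1"),
                  genetic_name = spec$id)
  if (spec$strand == "-") {
    genome_seq <- revcomp(genome_seq)
    g <- mirror_gene_model(g, L)
  }
  truth <- list(gene_id = spec$id, mechanism = truth_mech,
                expected_category = expected_category_for(
                  truth_mech, spec$cassette_frame_preserving),
                detail = detail)
  list(gene = g, genome = stats::setNames(genome_seq, chrom), truth = truth)
}

## genomic blocks (ascending) covering spliced range [from, to) of t
spliced_range_to_blocks <- function(t, from, to) {
  lens <- exon_lengths(t)
  cum <- cumsum(lens)
  blocks <- list()
  for (i in seq_len(nrow(t$exons))) {
    a <- if (i > 1L) cum[i - 1L] else 0L
    b <- cum[i]
    lo <- max(from, a); hi <- min(to, b)
    if (lo >= hi) next
    if (t$strand == "+") {
      gs <- t$exons[i, "start"] + (lo - a)
      blocks[[length(blocks) + 1L]] <- c(gs, gs + (hi - lo))
    } else {
      ge <- t$exons[i, "end"] - (lo - a)
      blocks[[length(blocks) + 1L]] <- c(ge - (hi - lo), ge)
    }
  }
  m <- do.call(rbind, blocks)
  colnames(m) <- c("start", "end")
  m[order(m[, "start"]), , drop = FALSE]
}

#' Generate transcript-support records for a synthetic gene
#'
#' Each record is drawn from a transcript according to the expression
#' weights. With probability `p_unspliced` an intronless record spanning the
#' transcript's genomic extent is emitted (a primary-transcript /
#' genomic-contamination artifact); otherwise with probability
#' `p_truncated_5p` the record's 5' end is cut at a uniform spliced position
#' (incomplete first-strand cDNA synthesis) and marked 5'-incomplete.
#' Library keys are assigned round-robin so co-sampled records count as
#' independent.
#'
#' @param gene A [gene_model()].
#' @param n Number of records.
#' @param weights Per-transcript weights (default uniform).
#' @param p_truncated_5p,p_unspliced Artifact probabilities.
#' @param libraries Library keys to cycle through.
#' @param min_keep Minimum spliced bases retained after truncation.
#' @return A [support_records()] data.frame.
#' @export
generate_ests <- function(gene, n, weights = NULL, p_truncated_5p = 0,
                          p_unspliced = 0,
                          libraries = paste0("lib", 1:6), min_keep = 40L) {
  txs <- gene$transcripts
  if (is.null(weights)) weights <- rep(1, length(txs))
  if (n == 0L) return(support_records(character(0), character(0), character(0),
                                      character(0), character(0), character(0)))
  pick <- sample(seq_along(txs), n, replace = TRUE, prob = weights)
  unspliced <- stats::runif(n) < p_unspliced
  truncated <- !unspliced & stats::runif(n) < p_truncated_5p
  rows <- lapply(seq_len(n), function(i) {
    t <- txs[[pick[i]]]
    if (unspliced[i]) {
      blocks <- encode_blocks(cbind(start = min(t$exons[, "start"]),
                                    end = max(t$exons[, "end"])))
      complete <- TRUE
    } else if (truncated[i]) {
      L <- transcript_length(t)
      cut <- sample.int(max(1L, L - min_keep), 1L)
      blocks <- encode_blocks(spliced_range_to_blocks(t, cut, L))
      complete <- FALSE
    } else {
      blocks <- encode_blocks(t$exons)
      complete <- TRUE
    }
    support_records(paste0(gene$id, "_est", i), "EST", gene$chrom,
                    gene$strand, blocks,
                    libraries[(i - 1L) %% length(libraries) + 1L],
                    five_prime_complete = complete)
  })
  do.call(rbind, rows)
}

## evidence guaranteeing the planted support level: ests_per_transcript
## full-length independent ESTs per transcript, plus artifact records at the
## given rates
generate_support <- function(gene, ests_per_transcript = 3L,
                             p_truncated_5p = 0, p_unspliced = 0,
                             libraries = paste0("lib", 1:6)) {
  rows <- list()
  k <- 0L
  for (t in gene$transcripts) {
    for (j in seq_len(ests_per_transcript)) {
      k <- k + 1L
      rows[[k]] <- support_records(
        paste0(gene$id, "_est", k), "EST", gene$chrom, gene$strand,
        encode_blocks(t$exons), libraries[(k - 1L) %% length(libraries) + 1L])
    }
  }
  base <- if (k > 0L) do.call(rbind, rows)
          else support_records(character(0), character(0), character(0),
                               character(0), character(0), character(0))
  n_art <- stats::rbinom(1L, max(k, 3L * length(gene$transcripts)),
                         min(1, p_truncated_5p + p_unspliced))
  if (p_truncated_5p + p_unspliced > 0 && n_art > 0L) {
    art <- generate_ests(gene, n_art,
                         p_truncated_5p = p_truncated_5p /
                           (p_truncated_5p + p_unspliced),
                         p_unspliced = p_unspliced /
                           (p_truncated_5p + p_unspliced),
                         libraries = libraries)
    art <- art[!art$five_prime_complete |
               vapply(art$blocks, function(b)
                 nrow(decode_blocks(b)) == 1L, TRUE), , drop = FALSE]
    if (nrow(art) > 0L) {
      art$id <- paste0(gene$id, "_art", seq_len(nrow(art)))
      base <- rbind(base, art)
    }
  }
  base
}

#' Generate a synthetic cohort
#'
#' Draws a mechanism per gene from the mixture, generates each locus on its
#' own reference sequence, and produces evidence with
#' `ests_per_transcript` independent full-length ESTs per transcript plus
#' artifact records at the spec'd rates. Fully reproducible from `seed`.
#'
#' @param n_genes Number of genes.
#' @param mixture Named mechanism proportions (must sum to 1); names from
#'   the mechanisms of [synthetic_gene_spec()].
#' @param seed Integer seed.
#' @param ests_per_transcript Independent full-length ESTs per transcript.
#' @param p_truncated_5p,p_unspliced Artifact rates.
#' @param strand Strand for all loci, or `"random"`.
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `evidence.tsv` and `truth.tsv`.
#' @param ... Further arguments passed to [synthetic_gene_spec()].
#' @return List with `genes` (named list), `genome` (named character
#'   vector), `evidence` (support-record data.frame) and `truth`
#'   (data.frame `gene_id`, `mechanism`, `expected_category`).
#' @export
generate_cohort <- function(n_genes, mixture = c(UNIQUE_START = 1),
                            seed = 1L, ests_per_transcript = 3L,
                            p_truncated_5p = 0, p_unspliced = 0,
                            strand = "+", dir = NULL, ...) {
  stopifnot(abs(sum(mixture) - 1) < 1e-8)
  set.seed(seed)
  mechs <- sample(names(mixture), n_genes, replace = TRUE, prob = mixture)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, n_genes)
  strands <- if (strand == "random") sample(c("+", "-"), n_genes, TRUE)
             else rep(strand, n_genes)
  genes <- list(); genome <- character(0); ev <- list(); truth <- list()
  for (i in seq_len(n_genes)) {
    gid <- sprintf("sg%04d", i)
    spec <- synthetic_gene_spec(mechanism = mechs[i], id = gid,
                                seed = gene_seeds[i], strand = strands[i],
                                p_truncated_5p = p_truncated_5p,
                                p_unspliced = p_unspliced, ...)
    out <- generate_gene(spec)
    genes[[gid]] <- out$gene
    genome <- c(genome, out$genome)
    ev[[i]] <- generate_support(out$gene, ests_per_transcript,
                                p_truncated_5p, p_unspliced)
    truth[[i]] <- data.frame(gene_id = gid, mechanism = mechs[i],
                             expected_category = out$truth$expected_category,
                             stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, ev)
  truth <- do.call(rbind, truth)
  res <- list(genes = genes, genome = genome, evidence = evidence,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_genome(genome, file.path(dir, "genome.fa"))
    write_gene_models(genes, file.path(dir, "annotation.gff3"))
    write_evidence(evidence, file.path(dir, "evidence.tsv"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  res
}
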