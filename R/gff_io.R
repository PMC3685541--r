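# GFF3 / FASTA input and output, built on rtracklayer and Biostrings.
# GFF3 is 1-based inclusive at the file boundary; everything internal is
# 0-based half-open.

#' Parse gene models from a GFF3 annotation
#'
#' Expects the standard `gene` / `mRNA` / `exon` / `CDS` feature hierarchy
#' with `ID`/`Parent` attributes. Exons of minus-strand transcripts are
#' re-ordered into transcript (5'->3') order. The CDS features of a
#' transcript (which include the termination codon) are collapsed into the
#' `cds_start`/`cds_end` endpoints.
#'
#' @param annotation Path to a GFF3 file.
#' @param genome Optional named [Biostrings::DNAStringSet]; when supplied,
#'   exon bounds are validated against sequence lengths.
#' @return A named list of [gene_model()] objects.
#' @export
parse_gene_models <- function(annotation, genome = NULL) {
  gr <- rtracklayer::import(annotation, format = "gff3")
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent))
    vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  else rep(NA_character_, length(gr))
  start0 <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))

  genes <- list()
  gidx <- which(type == "gene")
  midx <- which(type %in% c("mRNA", "transcript"))
  for (gi in gidx) {
    gid <- id[gi]
    tids <- id[midx][parent[midx] == gid]
    txs <- list()
    for (tid in tids) {
      ei <- which(type == "exon" & parent == tid)
      ci <- which(type == "CDS" & parent == tid)
      if (length(ei) == 0L) stop("transcript '", tid, "' has no exons")
      ex <- cbind(start = start0[ei], end = end0[ei])
      if (any(ex[, "start"] < start0[gi]) || any(ex[, "end"] > end0[gi]))
        stop("malformed annotation: exon of '", tid,
             "' outside the span of gene '", gid, "'")
      st <- strand[ei][1L]
      ex <- ex[order(ex[, "start"], decreasing = (st == "-")), , drop = FALSE]
      cds_start <- NA_integer_; cds_end <- NA_integer_
      if (length(ci)) {
        cl <- min(start0[ci]); cr <- max(end0[ci])
        covered <- all(vapply(ci, function(i) {
          any(ex[, "start"] <= start0[i] & end0[i] <= ex[, "end"])
        }, TRUE))
        if (!covered)
          stop("malformed annotation: CDS of '", tid, "' not contained in exons")
        if (st == "+") { cds_start <- cl; cds_end <- cr - 1L }
        else { cds_start <- cr - 1L; cds_end <- cl }
      }
      txs[[tid]] <- transcript(tid, chrom[gi], st, ex, cds_start, cds_end)
    }
    mol <- NA_character_; gen <- NA_character_
    if (!is.null(gr$molecular_name)) mol <- as.character(gr$molecular_name)[gi]
    if (!is.null(gr$genetic_name)) gen <- as.character(gr$genetic_name)[gi]
    genes[[gid]] <- gene_model(gid, txs, molecular_name = mol,
                               genetic_name = gen)
    if (!is.null(genome)) {
      slen <- nchar(genome_sequence(genome, chrom[gi]))
      if (genes[[gid]]$span["end"] > slen)
        stop("gene '", gid, "' extends beyond the end of sequence ", chrom[gi])
    }
  }
  genes
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [parse_gene_models()]: writing and re-parsing is the identity
#' on coordinates, strand and hierarchy.
#'
#' @param genes A list of [gene_model()] objects.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  rows <- list()
  add <- function(chrom, start0, end0, strand, type, ID = NA, Parent = NA,
                  phase = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start0 + 1L, end = end0, strand = strand,
      type = type, ID = ID, Parent = Parent, phase = phase,
      stringsAsFactors = FALSE)
  }
  for (g in genes) {
    add(g$chrom, g$span["start"], g$span["end"], g$strand, "gene", ID = g$id)
    for (t in g$transcripts) {
      add(g$chrom, min(t$exons[, "start"]), max(t$exons[, "end"]),
          t$strand, "mRNA", ID = t$id, Parent = g$id)
      ex <- t$exons[order(t$exons[, "start"]), , drop = FALSE]
      for (i in seq_len(nrow(ex)))
        add(g$chrom, ex[i, "start"], ex[i, "end"], t$strand, "exon",
            Parent = t$id)
      if (!is.na(t$cds_start)) {
        cl <- min(t$cds_start, t$cds_end)
        cr <- max(t$cds_start, t$cds_end) + 1L
        cum <- 0L  # CDS bases already emitted, in transcript order
        for (i in seq_len(nrow(t$exons))) {
          s <- max(t$exons[i, "start"], cl)
          e <- min(t$exons[i, "end"], cr)
          if (s < e) {
            add(g$chrom, s, e, t$strand, "CDS", Parent = t$id,
                phase = (3L - cum %% 3L) %% 3L)
            cum <- cum + (e - s)
          }
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand)
  gr$type <- df$type
  gr$phase <- df$phase
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome FASTA
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
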