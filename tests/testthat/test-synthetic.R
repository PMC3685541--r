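# Synthetic locus generator: determinism, structural guarantees, planted
# mechanisms, evidence artifact modes and cohort output schema.

test_that("the same spec and seed reproduce a byte-identical locus", {
  s1 <- generate_gene(synthetic_gene_spec(mechanism = "CASSETTE_EXON",
                                          id = "g", seed = 77L))
  s2 <- generate_gene(synthetic_gene_spec(mechanism = "CASSETTE_EXON",
                                          id = "g", seed = 77L))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$gene, s2$gene)
  s3 <- generate_gene(synthetic_gene_spec(mechanism = "CASSETTE_EXON",
                                          id = "g", seed = 78L))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("generated loci satisfy the structural contract", {
  for (s in 1:10) {
    mech <- sample(txiso:::SYNTH_MECHANISMS, 1L)
    out <- generate_gene(synthetic_gene_spec(mechanism = mech, id = "g",
                                             seed = s,
                                             strand = sample(c("+", "-"), 1L)))
    seqc <- out$genome[[1L]]
    for (t in out$gene$transcripts) {
      intr <- introns_of(t)
      for (i in seq_len(nrow(intr))) {
        don_acc <- if (t$strand == "+")
          c(substring(seqc, intr[i, "start"] + 1L, intr[i, "start"] + 2L),
            substring(seqc, intr[i, "end"] - 1L, intr[i, "end"]))
        else
          c(revcomp(substring(seqc, intr[i, "end"] - 1L, intr[i, "end"])),
            revcomp(substring(seqc, intr[i, "start"] + 1L, intr[i, "start"] + 2L)))
        expect_equal(don_acc, c("GT", "AG"), label = paste(mech, s, t$id, i))
      }
      cds <- cds_sequence(t, out$genome)
      expect_equal(substring(cds, 1L, 3L), "ATG")
      expect_equal(nchar(cds) %% 3L, 0L)
      expect_true(substring(cds, nchar(cds) - 2L) %in% c("TAA", "TAG", "TGA"))
    }
  }
})

test_that("productive transcripts terminate exactly at the annotated stop", {
  for (s in 1:10) {
    mech <- sample(c("NONE", "UNIQUE_START", "NESTED_START", "CASSETTE_EXON",
                     "RETAINED_INTRON", "SPLICE_SHIFT"), 1L)
    out <- generate_gene(synthetic_gene_spec(mechanism = mech, id = "g", seed = s))
    for (t in out$gene$transcripts) {
      tr <- translate_from(spliced_sequence(t, out$genome), cds_offset(t))
      expect_equal(tr$stop_offset, genomic_to_spliced(t, t$cds_end) - 2L,
                   label = paste(mech, s, t$id))
    }
  }
})

test_that("the planted mechanism is recovered by the matching detector", {
  for (s in 1:15) {
    ri <- generate_gene(synthetic_gene_spec(mechanism = "RETAINED_INTRON",
                                            id = "g", seed = s))
    calls <- find_retained_introns(ri$gene)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$intron_index, ri$truth$detail$intron_index)

    ss <- generate_gene(synthetic_gene_spec(mechanism = "SPLICE_SHIFT",
                                            id = "g", seed = s))
    sc <- find_splice_shifts(ss$gene)
    expect_equal(nrow(sc), 1L)
    expect_true(sc$offset %in% c(3L, 6L, 9L, 12L))
    expect_true(sc$frame_preserved)
  }
})

test_that("5'-truncation artifacts occur at the configured rate", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "UNIQUE_START",
                                           id = "g", seed = 50L))
  set.seed(123)
  recs <- generate_ests(out$gene, 1000L, p_truncated_5p = 0.5)
  frac <- mean(!recs$five_prime_complete)
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_equal(nrow(generate_ests(out$gene, 0L)), 0L)
  # rates 0 with weight on one transcript: all records match it exactly
  nt <- length(out$gene$transcripts)
  recs2 <- generate_ests(out$gene, 20L, weights = c(1, rep(0, nt - 1L)))
  t1 <- out$gene$transcripts[[1L]]
  expect_true(all(recs2$blocks == txiso:::encode_blocks(t1$exons)))
})

test_that("cohort files parse cleanly back through the package readers", {
  td <- withr::local_tempdir()
  coh <- generate_cohort(6L, mixture = c(UNIQUE_START = 0.5, RETAINED_INTRON = 0.5),
                         seed = 5L, dir = td, strand = "random")
  genome <- read_genome(file.path(td, "genome.fa"))
  genes <- parse_gene_models(file.path(td, "annotation.gff3"), genome)
  ev <- read_evidence(file.path(td, "evidence.tsv"))
  expect_length(genes, 6L)
  expect_setequal(names(genes), names(coh$genes))
  for (gid in names(genes)) {
    expect_identical(unname(genes[[gid]]$transcripts[[1L]]$exons),
                     unname(coh$genes[[gid]]$transcripts[[1L]]$exons))
  }
  expect_equal(nrow(ev), nrow(coh$evidence))
  expect_true(is.logical(ev$five_prime_complete))
  # determinism of the whole cohort
  coh2 <- generate_cohort(6L, mixture = c(UNIQUE_START = 0.5, RETAINED_INTRON = 0.5),
                          seed = 5L, strand = "random")
  expect_identical(coh$genome, coh2$genome)
  expect_identical(coh$evidence, coh2$evidence)
})

test_that("an artifact-free unique-start cohort is fully recovered end to end", {
  coh <- generate_cohort(10L, mixture = c(UNIQUE_START = 1), seed = 9L)
  res <- classify_cohort(coh$genes, coh$genome, coh$evidence)
  expect_true(all(res$category == "UNIQUE_START_STRONG"))
})
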