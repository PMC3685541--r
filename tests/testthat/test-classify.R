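# Gene-level classification: same-protein detection, discount rules,
# category assignment and cohort summaries.

test_that("transcripts differing only in untranslated regions encode the same protein", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "SAME_PROTEIN",
                                           id = "sp", seed = 3L))
  expect_true(encode_same_protein(out$gene, out$genome))
  # direct CDS string comparison as the oracle
  cds <- vapply(out$gene$transcripts, cds_sequence, "", genome = out$genome)
  expect_length(unique(cds), 1L)
  out2 <- generate_gene(synthetic_gene_spec(mechanism = "CASSETTE_EXON",
                                            id = "ce", seed = 3L))
  expect_false(encode_same_protein(out2$gene, out2$genome))
})

test_that("an alternative supported only by an unspliced read is discounted", {
  # t2 retains the single intron of t1 and equals the primary transcript
  genome <- c(chr = paste0("CC", "ATGAAA", "GT", strrep("ACT", 20), "AG",
                           "GGGCCCTAACC"))
  n1 <- 8L; i_end <- n1 + 64L
  t1 <- transcript("t1", "chr", "+", rbind(c(0L, n1), c(i_end, i_end + 11L)),
                   cds_start = 2L, cds_end = i_end + 8L)
  t2 <- transcript("t2", "chr", "+", rbind(c(0L, i_end + 11L)),
                   cds_start = 2L, cds_end = i_end + 8L)
  g <- gene_model("g", list(t1, t2))
  recs <- rbind(
    support_records(c("e1", "e2"), "EST", "chr", "+",
                    paste0("0-", n1, ";", i_end, "-", i_end + 11L),
                    c("libA", "libB")),
    support_records("u1", "EST", "chr", "+", paste0("0-", i_end + 11L), "libC"))
  res <- classify_gene(g, genome, recs)
  expect_equal(res$category, "DISCOUNTED")
  expect_true("UNSPLICED_PRIMARY" %in% unlist(res$discount_reasons))
})

test_that("a blocking upstream ATG discounts the proposed alternative start", {
  # nested alternative start whose 5' UTR holds an out-of-frame uATG with no
  # stop before the main start
  out <- generate_gene(synthetic_gene_spec(mechanism = "NESTED_START",
                                           id = "nb", seed = 11L))
  g <- out$gene
  genome <- out$genome
  t2 <- g$transcripts[[2L]]
  # give the nested transcript a short 5' UTR containing a blocking uATG
  utr_len <- 7L
  ex <- t2$exons
  ex[1L, "start"] <- ex[1L, "start"] - utr_len
  t2b <- transcript(t2$id, t2$chrom, "+", ex, t2$cds_start, t2$cds_end)
  s <- genome[[1L]]
  p <- ex[1L, "start"]
  substr(s, p + 1L, p + utr_len) <- "CCATGCC"   # uATG, out of frame, no stop
  genome[1L] <- s
  g2 <- gene_model(g$id, list(g$transcripts[[1L]], t2b))
  reasons <- apply_discount_rules(g2, genome,
                                  grade_evidence(assign_support(
                                    txiso:::generate_support(g2), g2), g2))
  expect_true("BLOCKING_UORF" %in% reasons[[t2$id]])
  res <- classify_gene(g2, genome, txiso:::generate_support(g2))
  expect_equal(res$category, "DISCOUNTED")
})

test_that("category assignment follows the priority order with evidence grades", {
  cfg <- classify_config()
  # alternative-promoter gene, every transcript with >= 2 independent ESTs
  out <- generate_gene(synthetic_gene_spec(mechanism = "UNIQUE_START",
                                           n_transcripts = 3L, id = "us", seed = 5L))
  res <- classify_gene(out$gene, out$genome, txiso:::generate_support(out$gene))
  expect_equal(res$category, "UNIQUE_START_STRONG")

  # retained intron carried by a single EST: weak
  out2 <- generate_gene(synthetic_gene_spec(mechanism = "RETAINED_INTRON",
                                            id = "ri", seed = 5L))
  txs <- out2$gene$transcripts
  n_ex <- vapply(txs, function(t) nrow(t$exons), 0L)
  spl <- txs[[which.max(n_ex)]]; ret <- txs[[which.min(n_ex)]]
  recs <- rbind(
    support_records(c("e1", "e2", "e3"), "EST", out2$gene$chrom, "+",
                    txiso:::encode_blocks(spl$exons), c("libA", "libB", "libC")),
    support_records("e4", "EST", out2$gene$chrom, "+",
                    txiso:::encode_blocks(ret$exons), "libD"))
  res2 <- classify_gene(out2$gene, out2$genome, recs)
  expect_equal(res2$category, "RETAINED_INTRON_WEAK")

  # several distinct mechanism types, all strong
  out3 <- generate_gene(synthetic_gene_spec(mechanism = "MULTIPLE",
                                            id = "mx", seed = 5L))
  res3 <- classify_gene(out3$gene, out3$genome, txiso:::generate_support(out3$gene))
  expect_equal(res3$category, "MULTIPLE_STRONG")

  # one distinct transcript only
  out4 <- generate_gene(synthetic_gene_spec(mechanism = "NONE", id = "n1", seed = 5L))
  expect_equal(classify_gene(out4$gene, out4$genome)$category, "NO_ALTERNATIVE")
})

test_that("repeated calls of one mechanism type stay a single-mechanism category", {
  # five unique starts remain 'alternative promoters', not 'multiple'
  out <- generate_gene(synthetic_gene_spec(mechanism = "UNIQUE_START",
                                           n_transcripts = 5L, id = "j1", seed = 9L))
  res <- classify_gene(out$gene, out$genome, txiso:::generate_support(out$gene))
  expect_equal(res$category, "UNIQUE_START_STRONG")
  expect_equal(unique(res$mechanisms$mechanism), "UNIQUE_START")
  expect_equal(nrow(res$mechanisms), 5L)
})

test_that("cohort summaries partition the cohort", {
  expect_true(all(summarize_cohort(data.frame(category = character(0)))$n == 0L))
  set.seed(19)
  coh <- generate_cohort(12L, mixture = c(UNIQUE_START = 0.4, CASSETTE_EXON = 0.3,
                                          RETAINED_INTRON = 0.3), seed = 19L)
  res <- classify_cohort(coh$genes, coh$genome, coh$evidence)
  sm <- summarize_cohort(res)
  expect_equal(sm$n[sm$category == "TOTAL"], 12L)
  expect_equal(sum(sm$n[sm$category != "TOTAL"]), 12L)
  # artifact-free cohorts recover the planted category
  expect_equal(res$category[match(coh$truth$gene_id, res$gene_id)],
               coh$truth$expected_category)
})
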