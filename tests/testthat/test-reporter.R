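# In-silico recombineering: edit application, reporter prediction,
# construct design and homology arms.

test_that("an empty edit set is the identity", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "NONE", id = "g", seed = 2L))
  ed <- apply_edits(out$gene, out$genome, list())
  expect_identical(ed$genome[[1L]], out$genome[[1L]])
  expect_identical(ed$gene$transcripts[[1L]]$exons,
                   out$gene$transcripts[[1L]]$exons)
  expect_null(ed$reporter_span)
})

test_that("an insertion shifts all downstream coordinates by its length", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "NONE", id = "g", seed = 2L))
  t0 <- out$gene$transcripts[[1L]]
  p <- t0$cds_start  # 1-base insertion immediately before the start codon
  ed <- apply_edits(out$gene, out$genome, list(edit_op("NT_INSERTION", p, "C")))
  t1 <- ed$gene$transcripts[[1L]]
  expect_equal(t1$cds_start, t0$cds_start + 1L)
  expect_equal(t1$cds_end, t0$cds_end + 1L)
  shifted <- t0$exons
  shifted[, "start"] <- shifted[, "start"] + (shifted[, "start"] >= p)
  shifted[, "end"] <- shifted[, "end"] + (shifted[, "end"] > p)
  expect_equal(unname(t1$exons), unname(shifted))
  # the local sequence context of every exon boundary is preserved
  expect_identical(spliced_sequence(t1, ed$genome),
                   paste0(substring(spliced_sequence(t0, out$genome), 1L,
                                    genomic_to_spliced(t0, p)),
                          "C",
                          substring(spliced_sequence(t0, out$genome),
                                    genomic_to_spliced(t0, p) + 1L)))
})

test_that("reporter placements after the start codon and before the stop are both valid", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "NONE", id = "g", seed = 4L))
  t0 <- out$gene$transcripts[[1L]]
  pay <- default_reporter_payload()
  for (p in c(t0$cds_start + 3L, t0$cds_end - 2L)) {
    ed <- apply_edits(out$gene, out$genome,
                      list(edit_op("REPORTER_INSERTION", p, pay)))
    pr <- predict_reporter(ed$gene, ed$genome, ed$reporter_span)
    expect_true(pr$expresses)
    expect_equal(pr$reason, "IN_FRAME")
  }
})

test_that("a +1 insertion 5' of a nested start frameshifts upstream transcripts only", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "NESTED_START",
                                           id = "g", seed = 6L))
  g <- out$gene
  nested <- g$transcripts[[2L]]
  host <- g$transcripts[[1L]]
  pay <- default_reporter_payload()
  edits <- list(edit_op("REPORTER_INSERTION", nested$cds_start + 3L, pay),
                edit_op("NT_INSERTION", nested$cds_start, "C"))
  ed <- apply_edits(g, out$genome, edits)
  pr <- predict_reporter(ed$gene, ed$genome, ed$reporter_span)
  expect_true(pr$expresses[pr$transcript_id == nested$id])
  expect_equal(pr$reason[pr$transcript_id == host$id], "FRAMESHIFTED_UPSTREAM")
  # without the extra base both transcripts express the reporter
  ed2 <- apply_edits(g, out$genome, edits[1L])
  pr2 <- predict_reporter(ed2$gene, ed2$genome, ed2$reporter_span)
  expect_true(all(pr2$expresses))
})

test_that("a single base in an optional exon knocks out exon-including transcripts", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "CASSETTE_EXON",
                                           id = "g", seed = 8L))
  g <- out$gene
  txs <- g$transcripts
  n_ex <- vapply(txs, function(t) nrow(t$exons), 0L)
  inc <- txs[[which.max(n_ex)]]; skp <- txs[[which.min(n_ex)]]
  cass_idx <- detect_mechanisms(g)
  cass_idx <- cass_idx[cass_idx$mechanism == "CASSETTE_EXON", ]
  e <- txs[[cass_idx$t1[1L]]]$exons[cass_idx$exon_index[1L], ]
  pay <- default_reporter_payload()
  edits <- list(edit_op("REPORTER_INSERTION",
                        if (g$strand == "+") inc$cds_end - 2L else inc$cds_end + 3L,
                        pay),
                edit_op("NT_INSERTION", (e["start"] + e["end"]) %/% 2L, "C"))
  ed <- apply_edits(g, out$genome, edits)
  pr <- predict_reporter(ed$gene, ed$genome, ed$reporter_span)
  expect_false(pr$expresses[pr$transcript_id == inc$id])
  expect_true(pr$expresses[pr$transcript_id == skp$id])
})

test_that("+1 followed by +2 at the same point restores the reading frame", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "NONE", id = "g", seed = 10L))
  t0 <- out$gene$transcripts[[1L]]
  pay <- default_reporter_payload()
  rep_edit <- edit_op("REPORTER_INSERTION", t0$cds_end - 2L, pay)
  mid <- spliced_to_genomic(t0, cds_offset(t0) + 30L)  # inside the CDS
  e1 <- apply_edits(out$gene, out$genome,
                    list(rep_edit, edit_op("NT_INSERTION", mid, "C")))
  expect_false(predict_reporter(e1$gene, e1$genome, e1$reporter_span)$expresses[1L])
  e2 <- apply_edits(out$gene, out$genome,
                    list(rep_edit, edit_op("NT_INSERTION", mid, "CAC")))
  expect_true(predict_reporter(e2$gene, e2$genome, e2$reporter_span)$expresses[1L])
})

test_that("overlapping edits and splice-dinucleotide hits are caught", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "NONE", id = "g", seed = 12L))
  t0 <- out$gene$transcripts[[1L]]
  expect_error(apply_edits(out$gene, out$genome,
                           list(edit_op("NT_INSERTION", 600L, "A"),
                                edit_op("NT_INSERTION", 600L, "C"))),
               "overlapping")
  intr <- introns_of(t0)
  expect_warning(apply_edits(out$gene, out$genome,
                             list(edit_op("NT_INSERTION",
                                          intr[1L, "start"] + 1L, "A"))),
                 "splice dinucleotide")
})

test_that("predict_reporter agrees with the codon-walk oracle on random cases", {
  for (i in 1:120) {
    case <- random_reporter_case(i)
    ed <- suppressWarnings(apply_edits(case$gene, case$genome, case$edits))
    pr <- predict_reporter(ed$gene, ed$genome, ed$reporter_span)
    for (tid in pr$transcript_id) {
      t <- ed$gene$transcripts[[tid]]
      expect_equal(pr$expresses[pr$transcript_id == tid],
                   oracle_reporter_expresses(t, ed$genome[[1L]],
                                             ed$reporter_span),
                   label = paste("case", i, tid))
    }
  }
})

test_that("terminal-fusion expression is the union of start-fusion expression", {
  for (s in 1:20) {
    out <- generate_gene(synthetic_gene_spec(
      mechanism = "UNIQUE_START", n_transcripts = sample(2:4, 1L),
      id = "g", seed = s))
    g <- out$gene
    pay <- default_reporter_payload()
    plus <- g$strand == "+"
    paygen <- if (plus) pay else revcomp(pay)
    term_pos <- if (plus) g$transcripts[[1L]]$cds_end - 2L
                else g$transcripts[[1L]]$cds_end + 3L
    edt <- apply_edits(g, out$genome,
                       list(edit_op("REPORTER_INSERTION", term_pos, paygen)))
    term <- predict_reporter(edt$gene, edt$genome, edt$reporter_span)
    starts_union <- rep(FALSE, length(g$transcripts))
    for (t in g$transcripts) {
      p <- if (plus) t$cds_start + 3L else t$cds_start - 2L
      eds <- apply_edits(g, out$genome,
                         list(edit_op("REPORTER_INSERTION", p, paygen)))
      pr <- predict_reporter(eds$gene, eds$genome, eds$reporter_span)
      starts_union <- starts_union | pr$expresses
    }
    expect_equal(term$expresses, starts_union, label = paste("seed", s))
  }
})

test_that("construct design collapses to the study's assay panel", {
  # three unique starts: three start tags plus the common terminal fusion
  loc <- example_unique_start_locus()
  des <- design_constructs(loc$gene, loc$genome, default_reporter_payload())
  expect_length(des$constructs, 4L)
  labels <- vapply(des$constructs, `[[`, "", "label")
  expect_equal(sum(startsWith(labels, "terminal")), 1L)
  expect_equal(sum(startsWith(labels, "start")), 3L)
  expect_length(des$inseparable, 0L)
  # every transcript pair is separated by some construct
  vecs <- do.call(rbind, lapply(des$constructs, `[[`, "vector"))
  for (i in 1:2) for (j in (i + 1):3)
    expect_true(any(vecs[, i] != vecs[, j]))

  # a single-transcript gene needs only the terminal fusion
  out1 <- generate_gene(synthetic_gene_spec(mechanism = "NONE", id = "g", seed = 3L))
  des1 <- design_constructs(out1$gene, out1$genome, default_reporter_payload())
  expect_length(des1$constructs, 1L)
  expect_true(startsWith(des1$constructs[[1L]]$label, "terminal"))
})

test_that("transcripts differing only by an in-frame site shift are inseparable", {
  out <- generate_gene(synthetic_gene_spec(mechanism = "SPLICE_SHIFT",
                                           id = "g", seed = 3L))
  des <- design_constructs(out$gene, out$genome, default_reporter_payload())
  expect_length(des$inseparable, 1L)
  expect_setequal(des$inseparable[[1L]], names(out$gene$transcripts))
})

test_that("homology arms flank the position and relocate it uniquely", {
  genome <- c(chr = paste(rep("ACGTT", 60), collapse = ""))
  ha <- homology_arms(genome, "chr", 100L, 50L)
  expect_equal(ha$upstream, substring(genome[[1L]], 51L, 100L))
  expect_equal(ha$downstream, substring(genome[[1L]], 101L, 150L))
  expect_error(homology_arms(genome, "chr", 20L, 50L), "too close")
  # arms from a random genome relocate the cut point uniquely
  set.seed(33)
  g2 <- c(chr = paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = ""))
  pos <- 1777L
  ha2 <- homology_arms(g2, "chr", pos, 50L)
  hit <- gregexpr(paste0(ha2$upstream, ha2$downstream), g2[[1L]],
                  fixed = TRUE)[[1L]]
  expect_equal(as.integer(hit), pos - 50L + 1L)
  # minus-strand arms are the reverse complements, swapped
  ha3 <- homology_arms(g2, "chr", pos, 50L, strand = "-")
  expect_equal(ha3$upstream, revcomp(ha2$downstream))
  expect_equal(ha3$downstream, revcomp(ha2$upstream))
})
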