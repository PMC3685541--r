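# Structural mechanism detectors: worked examples on toy coordinates,
# brute-force oracle equivalence on random exon-chain pairs, and the
# symmetry/strand-flip invariances.

test_that("disjoint first exons with a shared tail give one unique-start call each", {
  # three transcripts, crh-2-like alternative-promoter topology
  shared <- rbind(c(500L, 600L), c(700L, 800L))
  g <- mk_gene("g",
               mk_tx("a", rbind(c(0L, 80L), shared)),
               mk_tx("b", rbind(c(120L, 200L), shared)),
               mk_tx("c", rbind(c(250L, 330L), shared)))
  calls <- find_unique_starts(g)
  expect_equal(sort(calls$t1), c("a", "b", "c"))
  expect_true(all(calls$mechanism == "UNIQUE_START"))
  # single transcript: nothing to compare
  g1 <- mk_gene("g1", mk_tx("a", rbind(c(0L, 80L), shared)))
  expect_equal(nrow(find_unique_starts(g1)), 0L)
})

test_that("a first exon starting in another transcript's intron is a unique start", {
  # klf-3-like: a's first exon begins a few bases 5' of b's exon 2 and
  # overlaps no exon of b
  b <- mk_tx("b", rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L)))
  a <- mk_tx("a", rbind(c(180L, 196L), c(200L, 300L), c(400L, 500L)))
  g <- mk_gene("g", a, b)
  calls <- find_unique_starts(g)
  expect_true("a" %in% calls$t1)  # b's own upstream first exon also qualifies
})

test_that("nested starts require containment plus a junction suffix", {
  t1 <- mk_tx("t1", rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L)))
  t2 <- mk_tx("t2", rbind(c(250L, 300L), c(400L, 500L)))  # starts at 250 inside t1 exon 2
  g <- mk_gene("g", t1, t2)
  calls <- find_nested_starts(g)
  expect_equal(calls$t1, "t2")
  expect_equal(calls$host, "t1")
  expect_false(calls$acceptor_coincident)
  # identical transcripts: no nesting
  g2 <- mk_gene("g2", t1, mk_tx("t3", rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L))))
  expect_equal(nrow(find_nested_starts(g2)), 0L)
  # a nested start at a splice acceptor is recorded as such
  t4 <- mk_tx("t4", rbind(c(400L, 500L)))
  g3 <- mk_gene("g3", t1, t4)
  c3 <- find_nested_starts(g3)
  expect_true(c3$acceptor_coincident)
})

test_that("unique-start and nested-start are mutually exclusive per transcript", {
  set.seed(23)
  for (i in 1:100) {
    g <- random_toy_gene(i)
    us <- find_unique_starts(g)$t1
    ns <- find_nested_starts(g)$t1
    expect_length(intersect(us, ns), 0L)
  }
})

test_that("terminal-exon extensions into an intron are called with an NMD hint", {
  # nhr-104-like: b's final exon extends internal exon 2 of a into intron 2
  a <- mk_tx("a", rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L)))
  b <- mk_tx("b", rbind(c(0L, 100L), c(200L, 350L)))
  g <- mk_gene("g", a, b)
  calls <- find_alt_terminals(g)
  ext <- calls[calls$case == "extension", ]
  expect_equal(ext$t1, "b")
  expect_true(ext$nmd_hint)
  # all transcripts sharing the last exon: no call
  g2 <- mk_gene("g2", a, mk_tx("c", rbind(c(0L, 100L), c(400L, 500L))))
  expect_equal(nrow(find_alt_terminals(g2)), 0L)
})

test_that("retained introns are found with their transcript-order index", {
  a <- mk_tx("a", rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L)))
  b <- mk_tx("b", rbind(c(0L, 100L), c(200L, 500L)))  # retains intron 2 of a
  g <- mk_gene("g", a, b)
  calls <- find_retained_introns(g)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$t1, "a")
  expect_equal(calls$retained_in, "b")
  expect_equal(calls$intron_index, 2L)
  # no introns anywhere: no call
  g2 <- mk_gene("g2", mk_tx("a", rbind(c(0L, 100L))), mk_tx("b", rbind(c(0L, 90L))))
  expect_equal(nrow(find_retained_introns(g2)), 0L)
})

test_that("cassette exons are internal exons skipped over shared flanking junctions", {
  a <- mk_tx("a", rbind(c(0L, 100L), c(200L, 260L), c(400L, 500L)))
  b <- mk_tx("b", rbind(c(0L, 100L), c(400L, 500L)))
  g <- mk_gene("g", a, b)
  calls <- find_cassette_exons(g)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$t1, "a")
  expect_equal(calls$skipped_in, "b")
  expect_equal(calls$exon_index, 2L)
  # two cassette exons are both found
  a2 <- mk_tx("a", rbind(c(0L, 100L), c(200L, 260L), c(400L, 500L),
                         c(600L, 660L), c(800L, 900L)))
  b2 <- mk_tx("b", rbind(c(0L, 100L), c(400L, 500L), c(800L, 900L)))
  g2 <- mk_gene("g2", a2, b2)
  expect_equal(sort(find_cassette_exons(g2)$exon_index), c(2L, 4L))
})

test_that("splice-site shifts carry side, offset and frame preservation", {
  a <- mk_tx("a", rbind(c(0L, 100L), c(200L, 300L)))
  b3 <- mk_tx("b", rbind(c(0L, 100L), c(203L, 300L)))  # acceptor shifted by 3
  g <- mk_gene("g", a, b3)
  calls <- find_splice_shifts(g)
  expect_equal(calls$side, "acceptor")
  expect_equal(calls$offset, 3L)
  expect_true(calls$frame_preserved)
  # identical junctions: no call
  g0 <- mk_gene("g0", a, mk_tx("c", rbind(c(0L, 100L), c(200L, 300L))))
  expect_equal(nrow(find_splice_shifts(g0)), 0L)
  # donor shifted by 7: frame not preserved
  b7 <- mk_tx("d", rbind(c(0L, 93L), c(200L, 300L)))
  g7 <- mk_gene("g7", a, b7)
  c7 <- find_splice_shifts(g7)
  expect_equal(c7$side, "donor")
  expect_equal(c7$offset, 7L)
  expect_false(c7$frame_preserved)
})

test_that("every detector agrees with its brute-force oracle on random pairs", {
  for (i in 1:150) {
    g <- random_toy_gene(i)
    calls <- detect_mechanisms(g)
    keys <- call_keys(calls)
    expect_identical(keys$unique_start, oracle_unique_starts(g), label = paste("unique", i))
    expect_identical(keys$nested, oracle_nested_starts(g), label = paste("nested", i))
    expect_identical(keys$retained, oracle_retained_introns(g), label = paste("retained", i))
    expect_identical(keys$altterm, oracle_alt_terminals(g), label = paste("altterm", i))
    expect_identical(keys$cassette, oracle_cassette_exons(g), label = paste("cassette", i))
    expect_identical(keys$shift, oracle_splice_shifts(g), label = paste("shift", i))
  }
})

test_that("detectors are invariant under a strand flip of the whole locus", {
  for (i in 1:60) {
    g <- random_toy_gene(1000 + i)
    L <- max(vapply(g$transcripts, function(t) max(t$exons[, "end"]), 0L)) + 50L
    gm <- mirror_gene_model(g, L)
    a <- detect_mechanisms(g); b <- detect_mechanisms(gm)
    expect_equal(sort(a$mechanism), sort(b$mechanism), label = paste("flip", i))
    ka <- call_keys(a); kb <- call_keys(b)
    expect_identical(ka$unique_start, kb$unique_start)
    expect_identical(ka$nested, kb$nested)
    expect_identical(ka$retained, kb$retained)
    expect_identical(ka$cassette, kb$cassette)
    expect_identical(ka$shift, kb$shift)
  }
})
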