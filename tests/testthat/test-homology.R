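# The internal ungapped scanner and the species-scaled filtering rules.

test_that("internal_scan finds exact and 1-mismatch placements", {
  q <- data.frame(id = "m1", seq = "ACGT")
  h <- internal_scan(q, data.frame(id = "s", seq = "TTACGTTT"),
                     max_mismatch = 0, both_strands = FALSE)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$sstart, h$send), c(3L, 6L))
  expect_equal(h$pident, 100)
  expect_equal(hit_qcov(h), 1)

  h1 <- internal_scan(q, data.frame(id = "s", seq = "TTACGATT"),
                      max_mismatch = 1, both_strands = FALSE)
  expect_equal(h1$mismatches, 1L)
  expect_equal(h1$pident, 75)

  expect_error(internal_scan(data.frame(id = "e", seq = ""),
                             data.frame(id = "s", seq = "ACGT")), "empty")
  expect_error(internal_scan(data.frame(id = "q", seq = "ACGTACGT"),
                             data.frame(id = "s", seq = "ACGT")), "longer")
})

test_that("internal_scan matches brute-force window enumeration", {
  set.seed(101)
  for (rep in 1:8) {
    qseq <- rand_dna(21)
    sseq <- rand_dna(500)
    got <- internal_scan(data.frame(id = "q", seq = qseq),
                         data.frame(id = "s", seq = sseq),
                         max_mismatch = 1, both_strands = TRUE)
    want <- bf_scan(qseq, sseq, 1)
    expect_equal(got[, c("sstart", "send", "mismatches")],
                 want, ignore_attr = TRUE)
  }
})

test_that("filter_hits applies coverage and identity thresholds", {
  hits <- random_hits(1)
  hits$qlen <- 100L; hits$qstart <- 1L; hits$qend <- 95L; hits$pident <- 96
  expect_equal(nrow(filter_hits(hits, "wheat_marker")), 1)
  hits$qend <- 89L  # coverage 0.89 < 0.90
  expect_equal(nrow(filter_hits(hits, "wheat_marker")), 0)
  hits$qend <- 95L; hits$pident <- 94.9
  expect_equal(nrow(filter_hits(hits, "wheat_marker")), 0)

  expect_error(filter_hits(hits, "no_such_preset"), "valid presets")
})

test_that("filter_hits agrees with the predicate oracle and is monotone", {
  set.seed(202)
  hits <- random_hits(100)
  for (p in c("wheat_marker", "rice_marker", "rice_transcript")) {
    pr <- homology_preset(p)
    want <- hits[(hits$qend - hits$qstart + 1) / hits$qlen >= pr$min_qcov &
                   hits$pident >= pr$min_pident, ]
    expect_equal(filter_hits(hits, p), want, ignore_attr = TRUE)
  }
  # monotonicity: tightening never increases retention
  n_loose <- nrow(filter_hits(hits, list(min_qcov = .5, min_pident = 80)))
  n_tight <- nrow(filter_hits(hits, list(min_qcov = .5, min_pident = 90)))
  n_tighter <- nrow(filter_hits(hits, list(min_qcov = .8, min_pident = 90)))
  expect_true(n_tight <= n_loose)
  expect_true(n_tighter <= n_tight)
})

test_that("ambiguous markers are discarded, dominated rivals are not", {
  base <- random_hits(2)
  base$qid <- "m1"
  base$qlen <- 100L; base$qstart <- 1L; base$qend <- 95L
  base$sid <- c("chr3B", "chr5A")
  base$pident <- c(96, 96)
  base$bitscore <- c(180, 170)
  # equal coverage and identity at two locations: marker dropped
  expect_equal(nrow(drop_ambiguous_markers(base)), 0)
  # strict dominance: best hit kept
  base$pident <- c(96, 95)
  kept <- drop_ambiguous_markers(base)
  expect_equal(kept$sid, "chr3B")
  # single-hit marker: unchanged
  single <- base[1, ]
  expect_equal(drop_ambiguous_markers(single), single, ignore_attr = TRUE)
  # tandem split hits on one chromosome within 10 kb: not ambiguous
  tandem <- base
  tandem$pident <- c(96, 96)
  tandem$sid <- "chr3B"
  tandem$sstart <- c(1000L, 3000L); tandem$send <- c(1094L, 3094L)
  expect_equal(nrow(drop_ambiguous_markers(tandem)), 1)
  # idempotence
  expect_equal(drop_ambiguous_markers(kept), kept, ignore_attr = TRUE)
})

test_that("oat contig rule is strict on identity, inclusive on length", {
  h <- random_hits(3)
  h$sid <- c("ctg1", "ctg2", "ctg3")
  h$pident <- c(86, 85.0, 90)
  h$aln_len <- c(300L, 1000L, 299L)
  expect_equal(match_oat_contigs(h), "ctg1")
  expect_equal(match_oat_contigs(h[0, ]), character(0))
})

test_that("protein matches are filtered per database", {
  m <- data.frame(
    qid = c("p1", "p2", "p3", "p4"), sid = "x",
    similarity = c(55, 60, 80, 49.9),
    qcov = c(0.6, 0.9, 0.5, 0.9),
    db = c("uniprot_viridiplantae", "brachypodium", "brachypodium",
           "uniprot_viridiplantae"),
    stringsAsFactors = FALSE
  )
  kept <- filter_protein_matches(m)
  expect_equal(kept$qid, c("p1", "p3"))
  expect_equal(nrow(filter_protein_matches(m[0, ])), 0)
  m$db[1] <- "swissmodel"
  expect_error(filter_protein_matches(m), "unknown protein database")
})

test_that("cds_homology_hits reports ungapped identity for equal lengths", {
  set.seed(7)
  a <- rand_dna(300)
  b <- a
  substr(b, 10, 10) <- if (substr(a, 10, 10) == "A") "C" else "A"
  hits <- cds_homology_hits(
    data.frame(id = "q1", seq = a),
    data.frame(id = c("r1", "r2"), seq = c(b, rand_dna(200))))
  expect_equal(hits$sid, "r1")
  expect_equal(hits$mismatches, 1L)
  expect_equal(hits$pident, 100 * 299 / 300)
})
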