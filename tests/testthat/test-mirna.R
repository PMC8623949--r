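# Mature scanning, precursor folding and criteria, family summaries and
# target scoring.

test_that("family names normalize from miRBase-style ids", {
  expect_equal(mirna_family(c("tae-miR1122b-3p", "osa-miR444a.1",
                              "syn-miR9101a", "hvu-MIR156", "oddname")),
               c("miR1122", "miR444", "miR9101", "miR156", NA))
})

test_that("scan_matures finds planted matures within one mismatch", {
  set.seed(5)
  mat <- chartr("T", "U", rand_dna(21))
  matd <- chartr("U", "T", mat)
  locus <- paste0(rand_dna(200), matd, rand_dna(200))
  hits <- scan_matures(data.frame(id = "loc", seq = locus),
                       data.frame(id = "syn-miR9001a", seq = mat))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$start, 201L)
  expect_equal(plus$end, 221L)
  expect_equal(plus$mismatches, 0L)
  expect_equal(plus$family, "miR9001")

  # two substitutions: below the threshold, no hit
  mut <- matd
  substr(mut, 3, 3) <- setdiff(c("A", "C"), substr(mut, 3, 3))[1]
  substr(mut, 10, 10) <- setdiff(c("G", "T"), substr(mut, 10, 10))[1]
  locus2 <- paste0(rand_dna(100), mut, rand_dna(100))
  hits2 <- scan_matures(data.frame(id = "loc", seq = locus2),
                        data.frame(id = "syn-miR9001a", seq = mat))
  expect_equal(nrow(hits2), 0)

  expect_warning(
    scan_matures(data.frame(id = "loc", seq = locus),
                 data.frame(id = "short", seq = "ACGUACGUACGU")),
    "shorter than 18")
})

test_that("scan_matures equals brute-force enumeration and is strand-symmetric", {
  set.seed(6)
  locus <- rand_dna(1000)
  mats <- data.frame(id = sprintf("syn-miR%d", 9001:9005),
                     seq = chartr("T", "U",
                                  vapply(rep(21, 5), rand_dna, character(1))),
                     stringsAsFactors = FALSE)
  # embed two of them, one with a single substitution
  m1 <- chartr("U", "T", mats$seq[1])
  m2 <- chartr("U", "T", mats$seq[2])
  substr(m2, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(m2, 5, 5))[1]
  substr(locus, 100, 120) <- m1
  substr(locus, 500, 520) <- m2
  got <- scan_matures(data.frame(id = "loc", seq = locus), mats)
  for (i in seq_len(nrow(mats))) {
    want <- bf_scan(chartr("U", "T", mats$seq[i]), locus, 1)
    gi <- got[got$mature_id == mats$id[i], ]
    expect_equal(nrow(gi), nrow(want))
    if (nrow(want)) {
      expect_setequal(paste(gi$start, gi$end, gi$strand),
                      paste(pmin(want$sstart, want$send),
                            pmax(want$sstart, want$send),
                            ifelse(want$sstart <= want$send, "+", "-")))
    }
  }
  # strand symmetry: scanning the reverse complement mirrors the hit set
  rc <- data.frame(id = "loc_rc", seq = rc_dna(locus))
  got_rc <- scan_matures(rc, mats)
  n <- nchar(locus)
  expect_setequal(
    paste(got$mature_id, n - got$end + 1, n - got$start + 1,
          ifelse(got$strand == "+", "-", "+")),
    paste(got_rc$mature_id, got_rc$start, got_rc$end, got_rc$strand))
})

test_that("candidate windows anchor the mature at either arm and clip", {
  hit <- data.frame(mature_id = "m", family = "miR1", chrom = "loc",
                    start = 5000L, end = 5020L, strand = "+",
                    mismatches = 0L, stringsAsFactors = FALSE)
  locus <- data.frame(id = "loc", seq = rand_dna(6000))
  cands <- extract_candidates(hit, locus, window_lens = 150L)
  expect_equal(nrow(cands), 2)
  w5 <- cands[cands$arm == "5p", ]
  w3 <- cands[cands$arm == "3p", ]
  # anchored end keeps a 10-nt margin beyond the mature
  expect_equal(c(w5$start, w5$end), c(4990L, 5139L))
  expect_equal(c(w3$start, w3$end), c(4881L, 5030L))
  expect_equal(c(w5$mat_from, w5$mat_to), c(11L, 31L))
  expect_equal(c(w3$mat_from, w3$mat_to), c(120L, 140L))
  expect_false(any(cands$clipped))
  # the mature subsequence sits at the stated offsets
  expect_equal(substr(w5$seq, w5$mat_from, w5$mat_to),
               chartr("T", "U", substr(locus$seq, 5000, 5020)))

  # a hit 10 nt from the locus start: upstream window clipped and flagged
  hit2 <- hit
  hit2$start <- 11L; hit2$end <- 31L
  cands2 <- extract_candidates(hit2, locus, window_lens = 150L)
  w3c <- cands2[cands2$arm == "3p", ]
  expect_true(w3c$clipped)
  expect_equal(w3c$start, 1L)
})

test_that("fold_rna returns deterministic nested structures", {
  res <- fold_rna(c("GGGGGGAAAACCCCCC", strrep("A", 20)))
  expect_match(res$structure[1], "^\\(+\\.+\\)+$")
  expect_equal(res$structure[2], strrep(".", 20))
  expect_true(res$mfe[2] >= -0.5)
  expect_error(fold_rna("ACGTX"), "non-RNA")

  set.seed(12)
  seqs <- chartr("T", "U", vapply(rep(120, 5), rand_dna, character(1)))
  res2 <- fold_rna(seqs)
  for (i in 1:5) {
    p <- parse_dotbracket(res2$structure[i])  # errors if unbalanced
    # hairpin loop length >= 3 everywhere
    for (j in seq_along(p)) {
      if (p[j] > j) {
        inner <- p[(j + 1):(p[j] - 1)]
        if (all(inner == 0)) expect_true(p[j] - j - 1 >= 3)
      }
    }
  }
  expect_identical(fold_rna(seqs), res2)
})

test_that("parse_dotbracket validates balance", {
  expect_equal(parse_dotbracket("((..))"), c(6L, 5L, 0L, 0L, 2L, 1L))
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("(a)"), "invalid")
})

test_that("each hairpin criterion is evaluated independently", {
  set.seed(77)
  m <- random_mature(21)
  flags <- c("dicer_ok", "no_multibranch", "not_in_head",
             "duplex_mismatch_ok")
  cases <- list(none = NULL, dicer = "dicer_ok",
                multibranch = "no_multibranch", head = "not_in_head",
                duplex = "duplex_mismatch_ok")
  for (v in names(cases)) {
    mat <- if (v == "head") random_mature(21, head_foldback = TRUE) else m
    h <- make_hairpin(mat, v, verify = FALSE)
    ev <- evaluate_criteria(data.frame(seq = h$seq, mat_from = h$mat_from,
                                       mat_to = h$mat_to,
                                       stringsAsFactors = FALSE))
    intended <- setNames(rep(TRUE, 4), flags)
    if (!is.null(cases[[v]])) intended[cases[[v]]] <- FALSE
    expect_equal(unlist(ev[1, flags]), intended, info = v)
    expect_equal(ev$accepted, v == "none", info = v)
  }
})

test_that("evaluate_criteria rejects out-of-range mature spans", {
  expect_error(
    evaluate_criteria(data.frame(seq = "ACGUACGUACGU", mat_from = 5L,
                                 mat_to = 40L)),
    "outside")
})

test_that("overlapping same-family windows collapse to the lowest energy", {
  base <- data.frame(
    mature_id = "syn-miR9001a", family = "miR9001", chrom = "loc",
    start = c(100L, 100L, 5000L), end = c(249L, 299L, 5149L),
    strand = "+", arm = "5p", window_len = c(150L, 200L, 150L),
    seq = "N", mat_from = 1L, mat_to = 21L,
    hit_start = c(100L, 100L, 5000L), hit_end = c(120L, 120L, 5020L),
    clipped = FALSE, mfe = c(-30, -42.5, -28), accepted = TRUE,
    stringsAsFactors = FALSE)
  out <- dedupe_precursors(base)
  expect_equal(nrow(out), 2)
  # the two windows of one hairpin keep the lower-mfe representative
  expect_equal(out$mfe[out$start < 1000], -42.5)
  # non-overlapping same-family candidates both survive
  expect_true(5000L %in% out$start)
})

test_that("family partition matches set algebra and sums to the union", {
  p <- summarize_families(list(A = c("f1", "f2"), B = "f2"))
  expect_equal(p$partition$n_families[p$partition$members == "A"], 1L)
  expect_equal(p$partition$n_families[p$partition$members == "B"], 0L)
  expect_equal(p$partition$n_families[p$partition$members == "A+B"], 1L)
  expect_equal(p$total_families, 2L)

  same <- summarize_families(list(x = c("f1", "f2"), y = c("f1", "f2"),
                                  z = c("f1", "f2")))
  expect_equal(same$partition$n_families[same$partition$members == "x+y+z"],
               2L)
  expect_equal(sum(same$partition$n_families), same$total_families)

  # wheat genotypes merged into one set
  merged <- summarize_families(
    list(cs = "f1", svevo = c("f1", "f3"), barley = "f2"),
    merge_as = list(wheat = c("cs", "svevo")))
  expect_setequal(merged$families$wheat, c("f1", "f3"))
  expect_equal(merged$partition$n_families[
    merged$partition$members == "barley"], 1L)
})

test_that("target expectation reproduces forced arithmetic", {
  set.seed(42)
  mature <- "UGGACGUACGUAAGGCAUACG"
  site <- rc_dna(chartr("U", "T", mature))
  tx <- function(s) data.frame(id = "t1", seq = paste0(rand_dna(50), s,
                                                       rand_dna(50)))
  # perfect complement: expectation 0
  p0 <- score_target(mature, tx(site))
  expect_equal(min(p0$expectation), 0)
  expect_equal(p0$site_start[which.min(p0$expectation)], 51L)
  expect_true(all(p0$retained))

  # one G:U wobble in the seed: 0.5 * 2 = 1
  # mature position 5 (C) pairs site position L-4; make the target base A -> mismatch?
  # use G opposite mature U at seed position 3: U:G wobble
  site_wob <- site
  L <- nchar(mature)
  # mature position i pairs site offset L - i + 1 within the site
  i <- 3
  stopifnot(substr(mature, i, i) == "G")  # G:U wobble via target T
  substr(site_wob, L - i + 1, L - i + 1) <- "T"
  p1 <- score_target(mature, tx(site_wob))
  expect_equal(min(p1$expectation), 1)

  # one mismatch outside the seed (position 15): 1
  site_mm <- site
  j <- 15
  target_pos <- L - j + 1
  comp <- substr(site, target_pos, target_pos)
  substr(site_mm, target_pos, target_pos) <-
    setdiff(c("A", "C", "G", "T"), c(comp, "G", "T"))[1]
  p2 <- score_target(mature, tx(site_mm))
  expect_equal(min(p2$expectation), 1)

  # both edits together: 2, still retained at the default cutoff
  site_both <- site_wob
  substr(site_both, target_pos, target_pos) <-
    substr(site_mm, target_pos, target_pos)
  p3 <- score_target(mature, tx(site_both))
  expect_equal(min(p3$expectation), 2)
  expect_true(p3$retained[which.min(p3$expectation)])
})

test_that("site scoring matches the brute-force oracle", {
  set.seed(43)
  for (rep in 1:5) {
    mature <- chartr("T", "U", rand_dna(21))
    tseq <- rand_dna(300)
    want <- bf_score_sites(mature, tseq)
    got <- score_target(mature, data.frame(id = "t", seq = tseq),
                        max_report = Inf)
    expect_equal(got$expectation, unname(want[got$site_start]))
    expect_equal(nrow(got), length(want))
    expect_equal(got$retained, got$expectation <= 3)
  }
})
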