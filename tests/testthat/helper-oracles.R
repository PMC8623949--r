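# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths: the scanner
# oracle enumerates windows by hand, the filter oracle re-states the
# predicates as set comprehensions, and the target-score oracle walks the
# alignment base by base.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_dna <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# brute-force ungapped <=k-mismatch scan: every window, both strands
bf_scan <- function(qseq, sseq, k, both_strands = TRUE) {
  L <- nchar(qseq)
  n <- nchar(sseq)
  schars <- strsplit(sseq, "")[[1]]
  scan_one <- function(pat, minus) {
    pchars <- strsplit(pat, "")[[1]]
    out <- list()
    for (s in seq_len(n - L + 1)) {
      mm <- sum(pchars != schars[s:(s + L - 1)])
      if (mm <= k) {
        out[[length(out) + 1]] <- data.frame(
          sstart = if (minus) s + L - 1L else s,
          send = if (minus) s else s + L - 1L,
          mismatches = mm)
      }
    }
    do.call(rbind, out)
  }
  res <- scan_one(qseq, FALSE)
  if (both_strands) res <- rbind(res, scan_one(rc_dna(qseq), TRUE))
  if (is.null(res)) {
    res <- data.frame(sstart = integer(), send = integer(),
                      mismatches = integer())
  }
  res[order(pmin(res$sstart, res$send), res$sstart), , drop = FALSE]
}

# random alignment-hit table with controlled coverage/identity spread
random_hits <- function(n, chroms = c("chr1", "chr2", "chr3")) {
  qlen <- sample(60:200, n, replace = TRUE)
  cov <- round(runif(n, 0.3, 1), 3)
  qstart <- sample(1:10, n, replace = TRUE)
  qend <- pmin(qlen, qstart + ceiling(cov * qlen) - 1L)
  sstart <- sample(1:5e6, n, replace = TRUE)
  minus <- runif(n) < 0.5
  send <- sstart + (qend - qstart)
  tmp <- sstart
  sstart <- ifelse(minus, send, sstart)
  send <- ifelse(minus, tmp, send)
  data.frame(
    qid = sprintf("q%03d", sample(1:max(2, n %/% 3), n, replace = TRUE)),
    sid = sample(chroms, n, replace = TRUE),
    pident = round(runif(n, 60, 100), 2),
    aln_len = qend - qstart + 1L,
    mismatches = sample(0:10, n, replace = TRUE),
    gap_opens = 0L, qstart = qstart, qend = qend,
    sstart = sstart, send = send,
    evalue = 0, bitscore = round(runif(n, 50, 400), 1),
    qlen = qlen, slen = 1e7L, stringsAsFactors = FALSE
  )
}

# brute-force expectation scoring of every ungapped site
bf_score_sites <- function(mature, tseq, seed_positions = 2:13) {
  mature <- chartr("T", "U", toupper(mature))
  tseq <- toupper(tseq)
  L <- nchar(mature)
  mchars <- strsplit(mature, "")[[1]]
  tchars <- strsplit(tseq, "")[[1]]
  wc <- list(A = "T", C = "G", G = "C", U = "A")
  wobble <- list(G = "T", U = "G")
  out <- numeric(nchar(tseq) - L + 1)
  for (s in seq_along(out)) {
    e <- 0
    for (i in seq_len(L)) {
      tb <- tchars[s + L - i]
      pen <- if (identical(wc[[mchars[i]]], tb)) 0
      else if (identical(wobble[[mchars[i]]], tb)) 0.5
      else 1
      if (i %in% seed_positions) pen <- pen * 2
      e <- e + pen
    }
    out[s] <- e
  }
  out
}

# brute-force family sharing partition by set algebra
bf_partition <- function(sets) {
  genomes <- names(sets)
  all_fams <- sort(unique(unlist(sets)))
  subsets <- unlist(lapply(seq_along(genomes), function(k)
    combn(genomes, k, simplify = FALSE)), recursive = FALSE)
  vapply(subsets, function(sub) {
    inside <- Reduce(intersect, sets[sub], all_fams)
    outside <- unique(unlist(sets[setdiff(genomes, sub)]))
    length(setdiff(inside, outside))
  }, integer(1)) -> counts
  data.frame(members = vapply(subsets, paste, character(1), collapse = "+"),
             n_families = counts, stringsAsFactors = FALSE)
}

# tiny GFF3 text fixture: two genes on chr1 (one with 3-segment CDS, one with
# two isoforms), one gene on chr9, one orphan CDS
write_tiny_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=gene1",
    "chr1\ttest\tmRNA\t1000\t2000\t.\t+\t.\tID=t1.1;Parent=gene1",
    "chr1\ttest\tCDS\t1000\t1099\t.\t+\t0\tParent=t1.1",
    "chr1\ttest\tCDS\t1200\t1249\t.\t+\t0\tParent=t1.1",
    "chr1\ttest\tCDS\t1400\t1429\t.\t+\t0\tParent=t1.1",
    "chr1\ttest\tgene\t3000\t4000\t.\t-\t.\tID=gene2",
    "chr1\ttest\tmRNA\t3000\t4000\t.\t-\t.\tID=t2.1;Parent=gene2",
    "chr1\ttest\tCDS\t3000\t3299\t.\t-\t0\tParent=t2.1",
    "chr1\ttest\tmRNA\t3000\t4000\t.\t-\t.\tID=t2.2;Parent=gene2",
    "chr1\ttest\tCDS\t3000\t3449\t.\t-\t0\tParent=t2.2",
    "chr9\ttest\tgene\t100\t500\t.\t+\t.\tID=gene9",
    "chr9\ttest\tmRNA\t100\t500\t.\t+\t.\tID=t9.1;Parent=gene9",
    "chr9\ttest\tCDS\t100\t399\t.\t+\t0\tParent=t9.1",
    "chr1\ttest\tCDS\t5000\t5099\t.\t+\t0\tParent=missing_tx"
  ), path)
  path
}

# a locus gene table built directly (no GFF), for synteny tests
toy_locus_genes <- function(ids, cds_seqs, chrom = "chrT") {
  n <- length(ids)
  starts <- seq(1000, by = 2000, length.out = n)
  data.frame(
    gene_id = ids, chrom = chrom, start = starts, end = starts + 999,
    strand = "+", transcript_id = paste0(ids, ".t1"),
    cds_length = nchar(cds_seqs), cds_seq = cds_seqs, rank = seq_len(n),
    stringsAsFactors = FALSE
  )
}
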