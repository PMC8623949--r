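# Homology-hit generation and the species-scaled filtering rules.
#
# Real-data workflows feed externally generated 14-column hit tables through
# read_hit_table(); for desk-scale and synthetic inputs the package ships an
# internal ungapped <=k-mismatch scanner (internal_scan) which is also what
# the miRNA mature scan builds on.

#' Built-in homology filter presets
#'
#' Thresholds are scaled by evolutionary distance from wheat. Contexts:
#' `marker` — QTL marker panels mapped onto assemblies (90% query coverage;
#' identity 95/90/85/80 for wheat / barley+rye / oat / rice);
#' `transcript` — transcript projection and cross-genome transcript
#' comparison (80% query coverage; identity 95/90 for wheat / barley+rye, and
#' coverage relaxed to 50% with identity 80 for rice);
#' `cds` — CDS-vs-transcript region identification (rice 50%/80, barley
#' 80%/90).
#'
#' @return data.frame with columns `name`, `context`, `min_qcov` (fraction)
#'   and `min_pident` (percent)
#' @examples
#' homology_presets()
#' @export
homology_presets <- function() {
  data.frame(
    name = c("wheat_marker", "barley_rye_marker", "oat_marker", "rice_marker",
             "wheat_transcript", "barley_rye_transcript", "rice_transcript",
             "rice_cds", "barley_cds"),
    context = c(rep("marker", 4), rep("transcript", 3), "cds", "cds"),
    min_qcov = c(0.90, 0.90, 0.90, 0.90, 0.80, 0.80, 0.50, 0.50, 0.80),
    min_pident = c(95, 90, 85, 80, 95, 90, 80, 80, 90),
    stringsAsFactors = FALSE
  )
}

#' Look up (or build) a filter preset
#'
#' @param preset a preset name from [homology_presets()], or a list/one-row
#'   data.frame with fields `min_qcov` and `min_pident`
#' @return one-row data.frame with `name`, `min_qcov`, `min_pident`
#' @export
homology_preset <- function(preset) {
  if (is.character(preset)) {
    tab <- homology_presets()
    i <- match(preset, tab$name)
    if (is.na(i)) {
      stop("unknown preset '", preset, "'; valid presets: ",
           paste(tab$name, collapse = ", "))
    }
    return(tab[i, , drop = FALSE])
  }
  stopifnot(!is.null(preset$min_qcov), !is.null(preset$min_pident),
            preset$min_qcov > 0, preset$min_qcov <= 1,
            preset$min_pident > 0, preset$min_pident <= 100)
  data.frame(name = preset$name %||% "custom",
             min_qcov = preset$min_qcov, min_pident = preset$min_pident,
             stringsAsFactors = FALSE)
}

#' Query coverage of alignment hits
#'
#' Computed from `qstart`/`qend` (not `aln_len`, which gaps inflate).
#'
#' @param hits hit data.frame
#' @return numeric vector of fractions in \[0, 1\]
#' @export
hit_qcov <- function(hits) (hits$qend - hits$qstart + 1) / hits$qlen

#' Subject strand of alignment hits ("+" when sstart <= send)
#' @param hits hit data.frame
#' @return character vector of "+"/"-"
#' @export
hit_strand <- function(hits) ifelse(hits$sstart <= hits$send, "+", "-")

#' Ungapped <=k-mismatch scan of a query against a subject
#'
#' Reports every full-length ungapped placement of the query (and of its
#' reverse complement when `both_strands`) with at most `max_mismatch`
#' substitutions, as standard alignment-hit rows: query coverage is always 1,
#' `pident = 100 * (1 - mismatches/qlen)`, and minus-strand placements carry
#' `sstart > send`. Matching is delegated to
#' [Biostrings::matchPattern()] with `with.indels = FALSE`; positions
#' containing N never match.
#'
#' @param query,subject one-row sequence-record data.frames (or any list with
#'   `id` and `seq`), DNA
#' @param max_mismatch maximum number of substitutions
#' @param both_strands also scan the reverse complement of the query
#' @return hit data.frame (see [read_hit_table()] for columns)
#' @examples
#' q <- data.frame(id = "m1", seq = "ACGT")
#' s <- data.frame(id = "chr", seq = "TTACGTTT")
#' internal_scan(q, s, max_mismatch = 0)
#' @export
internal_scan <- function(query, subject, max_mismatch = 0L,
                          both_strands = TRUE) {
  qseq <- toupper(query$seq[[1]])
  sseq <- toupper(subject$seq[[1]])
  if (is.null(qseq) || !nzchar(qseq)) stop("empty query sequence")
  if (nchar(qseq) > nchar(sseq)) {
    stop("query longer than subject (", nchar(qseq), " > ", nchar(sseq), ")")
  }
  subj <- Biostrings::DNAString(sseq)
  qlen <- nchar(qseq)
  slen <- nchar(sseq)

  one_strand <- function(pat, minus) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)
    if (length(m) == 0) return(empty_hits())
    starts <- Biostrings::start(m)
    ends <- Biostrings::end(m)
    mm <- vapply(seq_along(starts), function(i) {
      hamming(pat, as.character(Biostrings::subseq(subj, starts[i], ends[i])))
    }, integer(1))
    data.frame(
      qid = query$id[[1]], sid = subject$id[[1]],
      pident = 100 * (1 - mm / qlen), aln_len = qlen, mismatches = mm,
      gap_opens = 0L, qstart = 1L, qend = qlen,
      sstart = if (minus) ends else starts,
      send = if (minus) starts else ends,
      evalue = 0, bitscore = 2 * (qlen - mm), qlen = qlen, slen = slen,
      stringsAsFactors = FALSE
    )
  }

  out <- one_strand(qseq, minus = FALSE)
  if (both_strands) {
    out <- rbind(out, one_strand(revcomp_dna(qseq), minus = TRUE))
  }
  out <- out[order(pmin(out$sstart, out$send), out$sstart), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a panel of queries against a set of subjects
#'
#' Convenience wrapper around [internal_scan()] for marker panels versus
#' chromosomes. Queries longer than a subject are skipped.
#'
#' @param queries,subjects sequence-record data.frames
#' @inheritParams internal_scan
#' @return combined hit data.frame
#' @export
scan_panel <- function(queries, subjects, max_mismatch = 0L,
                       both_strands = TRUE) {
  out <- list()
  for (i in seq_len(nrow(queries))) {
    for (j in seq_len(nrow(subjects))) {
      if (nchar(queries$seq[i]) > nchar(subjects$seq[j])) next
      out[[length(out) + 1]] <- internal_scan(
        queries[i, ], subjects[j, ], max_mismatch = max_mismatch,
        both_strands = both_strands)
    }
  }
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter hits by a coverage/identity preset
#'
#' Retains hits with query coverage `>= min_qcov` and percent identity
#' `>= min_pident`.
#'
#' @param hits hit data.frame
#' @param preset preset name or list, see [homology_preset()]
#' @return filtered hit data.frame
#' @examples
#' # a 96%-identity hit covering 95% of the marker passes the wheat preset
#' @export
filter_hits <- function(hits, preset) {
  p <- homology_preset(preset)
  keep <- hit_qcov(hits) >= p$min_qcov & hits$pident >= p$min_pident
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop markers with ambiguous best placements; keep one best hit otherwise
#'
#' A marker mapping to two or more distinct locations with identical (query
#' coverage, percent identity) at its maximum is discarded entirely; otherwise
#' only its single best hit (by coverage, then identity, then bitscore) is
#' kept. "Distinct locations" means different chromosomes, or intervals on the
#' same chromosome separated by at least `min_gap` bp — split/tandem hits
#' closer than that do not discard a marker.
#'
#' @param hits threshold-filtered hit data.frame
#' @param min_gap bp separation on one chromosome that counts as a distinct
#'   location
#' @return hit data.frame with at most one row per query
#' @export
drop_ambiguous_markers <- function(hits, min_gap = 1e4) {
  if (nrow(hits) == 0) return(hits)
  qcov <- hit_qcov(hits)
  s_lo <- pmin(hits$sstart, hits$send)
  s_hi <- pmax(hits$sstart, hits$send)
  keep_rows <- integer(0)
  for (q in unique(hits$qid)) {
    idx <- which(hits$qid == q)
    o <- idx[order(-qcov[idx], -hits$pident[idx], -hits$bitscore[idx],
                   hits$sid[idx], s_lo[idx])]
    best <- o[1]
    # rivals: same (qcov, pident) as the best, at a distinct location
    rivals <- o[-1]
    rivals <- rivals[abs(qcov[rivals] - qcov[best]) < 1e-9 &
                       abs(hits$pident[rivals] - hits$pident[best]) < 1e-9]
    distinct <- vapply(rivals, function(r) {
      hits$sid[r] != hits$sid[best] ||
        (s_lo[r] > s_hi[best] + min_gap) || (s_lo[best] > s_hi[r] + min_gap)
    }, logical(1))
    if (!any(distinct)) keep_rows <- c(keep_rows, best)
  }
  out <- hits[sort(keep_rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Oat contig matching rule
#'
#' Because oat contigs are genomic (intron-containing), transcript matches are
#' judged locally: a contig is retained when it has at least one hit with
#' percent identity strictly above `min_pident` over at least `min_aln_len`
#' aligned nucleotides.
#'
#' @param hits transcript-vs-contig hit data.frame
#' @param min_pident identity threshold (strict, default 85)
#' @param min_aln_len minimum aligned length in nt (default 300)
#' @return sorted character vector of retained contig ids
#' @export
match_oat_contigs <- function(hits, min_pident = 85, min_aln_len = 300L) {
  if (nrow(hits) == 0) return(character(0))
  sort(unique(hits$sid[hits$pident > min_pident &
                         hits$aln_len >= min_aln_len]))
}

#' Filter protein annotation matches
#'
#' Uniprot (Viridiplantae) matches require at least 50% sequence similarity
#' and 50% query coverage; Brachypodium proteome matches require at least 75%
#' similarity and 50% coverage (closer evolutionary distance).
#'
#' @param matches data.frame with columns `qid`, `sid`, `similarity`
#'   (percent), `qcov` (fraction) and `db` (`"uniprot_viridiplantae"` or
#'   `"brachypodium"`)
#' @return filtered data.frame
#' @export
filter_protein_matches <- function(matches) {
  if (nrow(matches) == 0) return(matches)
  known <- c("uniprot_viridiplantae", "brachypodium")
  bad <- setdiff(unique(matches$db), known)
  if (length(bad)) {
    stop("unknown protein database label(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(known, collapse = " or "))
  }
  min_sim <- ifelse(matches$db == "brachypodium", 75, 50)
  out <- matches[matches$similarity >= min_sim & matches$qcov >= 0.5, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ungapped CDS-vs-CDS homology hits for desk-scale data
#'
#' Compares every query CDS against every reference CDS of equal length with
#' a full-length ungapped (Hamming) alignment and emits standard hit rows for
#' pairs at or above `min_pident`. Intended for synthetic or desk-scale
#' fixtures where orthologous coding sequences differ by substitutions only;
#' gapped homology on real data should come from an external aligner via
#' [read_hit_table()].
#'
#' @param queries,refs sequence-record data.frames of coding sequences
#' @param min_pident minimum percent identity to report (default 50)
#' @return hit data.frame
#' @export
cds_homology_hits <- function(queries, refs, min_pident = 50) {
  out <- list()
  qlens <- nchar(queries$seq)
  rlens <- nchar(refs$seq)
  for (i in seq_len(nrow(queries))) {
    js <- which(rlens == qlens[i])
    for (j in js) {
      mm <- hamming(queries$seq[i], refs$seq[j])
      pid <- 100 * (1 - mm / qlens[i])
      if (pid < min_pident) next
      out[[length(out) + 1]] <- data.frame(
        qid = queries$id[i], sid = refs$id[j], pident = pid,
        aln_len = qlens[i], mismatches = mm, gap_opens = 0L,
        qstart = 1L, qend = qlens[i], sstart = 1L, send = qlens[i],
        evalue = 0, bitscore = 2 * (qlens[i] - mm),
        qlen = qlens[i], slen = rlens[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
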