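# Turning filtered homology hits into homologous-locus intervals.

#' Single-linkage continuity filter for hits on a chromosome
#'
#' Clusters position-normalized hits by single linkage with inter-hit gap at
#' most `max_gap`, and retains only the dominant cluster — the one supported
#' by the most distinct queries (ties broken by higher summed bitscore, then
#' by leftmost position). Hits on several chromosomes are clustered per
#' chromosome independently. Used when a homologous region is identified from
#' transcript projections whose lower thresholds admit scattered paralog hits:
#' only matches forming a continuous interval are retained.
#'
#' @param hits hit data.frame
#' @param max_gap maximum gap in bp between neighbouring hits of one cluster
#'   (default 2 Mb, the transcript-projection default; sparse marker panels
#'   typically use 5 Mb)
#' @return subset of `hits` (dominant cluster per chromosome)
#' @export
continuity_filter <- function(hits, max_gap = 2e6) {
  if (nrow(hits) == 0) return(hits)
  s_lo <- pmin(hits$sstart, hits$send)
  s_hi <- pmax(hits$sstart, hits$send)
  keep <- integer(0)
  for (chr in unique(hits$sid)) {
    idx <- which(hits$sid == chr)
    o <- idx[order(s_lo[idx], s_hi[idx])]
    cl <- integer(length(o))
    cl[1] <- 1L
    run_max <- s_hi[o[1]]
    for (k in seq_along(o)[-1]) {
      if (s_lo[o[k]] - run_max > max_gap) {
        cl[k] <- cl[k - 1] + 1L
      } else {
        cl[k] <- cl[k - 1]
      }
      run_max <- max(run_max, s_hi[o[k]])
      if (cl[k] != cl[k - 1]) run_max <- s_hi[o[k]]
    }
    support <- tapply(hits$qid[o], cl, function(x) length(unique(x)))
    score <- tapply(hits$bitscore[o], cl, sum)
    lo <- tapply(s_lo[o], cl, min)
    ord <- order(-as.vector(support), -as.vector(score), as.vector(lo))
    best_cl <- as.integer(names(support))[ord[1]]
    keep <- c(keep, o[cl == best_cl])
  }
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer homologous-locus intervals from filtered hits
#'
#' Hits are grouped by subject chromosome; every chromosome supported by at
#' least `min_support` distinct queries yields one interval spanning from the
#' minimum to the maximum strand-normalized subject position of its hits.
#' Borders snap to hit extremes (not to gene boundaries); a single spurious
#' hit cannot nominate a region.
#'
#' @param hits filtered, disambiguated hit data.frame
#' @param min_support minimum number of distinct supporting queries per
#'   chromosome (default 3)
#' @param genome genome label carried into the output
#' @param method `"marker"` or `"transcript_projection"`
#' @return data.frame with columns `genome`, `chrom`, `start`, `end`,
#'   `support`, `method`; zero rows when nothing passes
#' @export
infer_interval <- function(hits, min_support = 3L, genome = NA_character_,
                           method = c("marker", "transcript_projection")) {
  method <- match.arg(method)
  empty <- data.frame(genome = character(), chrom = character(),
                      start = integer(), end = integer(),
                      support = integer(), method = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  s_lo <- pmin(hits$sstart, hits$send)
  s_hi <- pmax(hits$sstart, hits$send)
  rows <- lapply(sort(unique(hits$sid)), function(chr) {
    idx <- which(hits$sid == chr)
    support <- length(unique(hits$qid[idx]))
    if (support < min_support) return(NULL)
    data.frame(genome = genome, chrom = chr,
               start = min(s_lo[idx]), end = max(s_hi[idx]),
               support = support, method = method, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Jaccard overlap of two intervals on the same chromosome
#' @param a,b lists or one-row data.frames with `start`, `end`
#' @return numeric scalar in \[0, 1\]
#' @export
interval_jaccard <- function(a, b) {
  inter <- max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
  uni <- max(a$end, b$end) - min(a$start, b$start) + 1
  inter / uni
}
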