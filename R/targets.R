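# miRNA target scoring: weighted complementarity penalty ("expectation")
# between a mature miRNA and candidate sites on a transcript.

# penalty of mature base m against target (transcript) base t:
# Watson-Crick pair = 0, G:U wobble = 0.5, otherwise 1.
pair_penalty_matrix <- function() {
  bases_m <- c("A", "C", "G", "U")
  bases_t <- c("A", "C", "G", "T")
  p <- matrix(1, 4, 4, dimnames = list(bases_m, bases_t))
  p["A", "T"] <- 0
  p["U", "A"] <- 0
  p["G", "C"] <- 0
  p["C", "G"] <- 0
  p["G", "T"] <- 0.5  # G pairs U in the target
  p["U", "G"] <- 0.5
  p
}

#' Score candidate target sites of a mature miRNA on a transcript
#'
#' Slides the mature (RNA, 5'->3') along every ungapped site of the
#' transcript (DNA CDS, plus strand) in reverse-complement orientation and
#' computes the expectation penalty: mismatch = 1, G:U wobble = 0.5, with
#' every penalty doubled at mature positions 2-13 (the seed region). Sites
#' are reported 5'->3' on the transcript; a site is `retained` iff its
#' expectation is at most `max_expectation`. Site accessibility (UPE) is not
#' computed; the expectation filter is the operative criterion and the
#' disabled accessibility cutoff is recorded in pipeline reports.
#'
#' @param mature RNA string, or a one-row sequence-record data.frame
#' @param transcript DNA sequence-record data.frame (one row)
#' @param max_expectation retention cutoff (default 3)
#' @param max_report only sites with expectation `<= max_report` are
#'   returned (default `max_expectation`; use `Inf` to enumerate all sites)
#' @param seed_positions mature positions whose penalties are doubled
#' @return data.frame with columns `mature_id`, `transcript_id`, `site_start`,
#'   `site_end` (1-based on the transcript), `expectation`, `retained`
#' @export
score_target <- function(mature, transcript, max_expectation = 3,
                         max_report = max_expectation,
                         seed_positions = 2:13) {
  if (is.data.frame(mature)) {
    mature_id <- mature$id[[1]]
    mseq <- mature$seq[[1]]
  } else {
    mature_id <- "mature"
    mseq <- mature
  }
  mseq <- dna_to_rna(toupper(mseq))
  tseq <- toupper(transcript$seq[[1]])
  tid <- transcript$id[[1]]
  L <- nchar(mseq)
  n <- nchar(tseq)
  empty <- data.frame(mature_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      expectation = numeric(), retained = logical(),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  pmat <- pair_penalty_matrix()
  weights <- rep(1, L)
  weights[intersect(seed_positions, seq_len(L))] <- 2

  mchars <- strsplit(mseq, "", fixed = TRUE)[[1]]
  tchars <- strsplit(tseq, "", fixed = TRUE)[[1]]
  mi <- match(mchars, rownames(pmat))
  ti <- match(tchars, colnames(pmat))
  if (anyNA(mi)) stop("mature contains non-ACGU characters")

  n_sites <- n - L + 1
  exp_vals <- numeric(n_sites)
  # mature position i pairs transcript position s + L - i for a site [s, s+L-1]
  for (i in seq_len(L)) {
    tpos <- (seq_len(n_sites)) + L - i
    pen <- pmat[cbind(rep(mi[i], n_sites), ti[tpos])]
    pen[is.na(pen)] <- 1  # N or unknown base: mismatch
    exp_vals <- exp_vals + weights[i] * pen
  }
  keep <- which(exp_vals <= max_report)
  if (!length(keep)) return(empty)
  data.frame(mature_id = mature_id, transcript_id = tid,
             site_start = keep, site_end = keep + L - 1L,
             expectation = exp_vals[keep],
             retained = exp_vals[keep] <= max_expectation,
             stringsAsFactors = FALSE)
}

#' Score all mature/transcript combinations
#'
#' @param matures RNA sequence-record data.frame
#' @param transcripts DNA sequence-record data.frame (CDS set)
#' @inheritParams score_target
#' @return combined prediction data.frame (see [score_target()])
#' @export
score_targets <- function(matures, transcripts, max_expectation = 3,
                          max_report = max_expectation) {
  out <- list()
  for (i in seq_len(nrow(matures))) {
    for (j in seq_len(nrow(transcripts))) {
      p <- score_target(matures[i, ], transcripts[j, ],
                        max_expectation = max_expectation,
                        max_report = max_report)
      if (nrow(p)) out[[length(out) + 1]] <- p
    }
  }
  if (!length(out)) {
    return(data.frame(mature_id = character(), transcript_id = character(),
                      site_start = integer(), site_end = integer(),
                      expectation = numeric(), retained = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
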