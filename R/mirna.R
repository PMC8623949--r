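# Homology-based miRNA discovery inside locus intervals: mature-sequence
# scanning (<=1 mismatch), precursor window extraction, thermodynamic folding,
# hairpin criteria evaluation, deduplication and family summarization.

#' Normalize a miRBase-style mature id to its family name
#'
#' Strips the species prefix and any letter/arm suffixes after the family
#' numeral: `"tae-miR1122b-3p"` becomes `"miR1122"`.
#'
#' @param mature_id character vector of miRBase-style ids
#' @return character vector of family names (`NA` when no family numeral is
#'   found)
#' @export
mirna_family <- function(mature_id) {
  m <- regexpr("(?i)mir-?[0-9]+", mature_id, perl = TRUE)
  fam <- rep(NA_character_, length(mature_id))
  ok <- m > 0
  txt <- regmatches(mature_id, m)
  fam[ok] <- paste0("miR", sub("(?i)mir-?", "", txt, perl = TRUE))
  fam
}

#' Scan a locus for mature miRNA matches (at most one mismatch)
#'
#' Finds every window on both strands of `locus_seq` within Hamming distance
#' `max_mismatch` (default 1) of any mature in the reference set. Matures are
#' RNA and are mapped to DNA internally; matures shorter than 18 nt raise a
#' warning but are still scanned.
#'
#' @param locus_seq one-row DNA sequence-record data.frame (a locus
#'   subsequence or chromosome)
#' @param matures RNA sequence-record data.frame with miRBase-style ids
#' @param max_mismatch maximum Hamming distance (default 1)
#' @return data.frame with columns `mature_id`, `family`, `chrom`, `start`,
#'   `end`, `strand`, `mismatches`
#' @export
scan_matures <- function(locus_seq, matures, max_mismatch = 1L) {
  short <- nchar(matures$seq) < 18
  if (any(short)) {
    warning("mature sequence(s) shorter than 18 nt: ",
            paste(matures$id[short], collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(matures))) {
    q <- data.frame(id = matures$id[i],
                    seq = rna_to_dna(toupper(matures$seq[i])),
                    stringsAsFactors = FALSE)
    if (nchar(q$seq) > nchar(locus_seq$seq[[1]])) next
    h <- internal_scan(q, locus_seq, max_mismatch = max_mismatch,
                       both_strands = TRUE)
    if (nrow(h) == 0) next
    out[[length(out) + 1]] <- data.frame(
      mature_id = h$qid, family = mirna_family(h$qid),
      chrom = h$sid, start = pmin(h$sstart, h$send),
      end = pmax(h$sstart, h$send), strand = hit_strand(h),
      mismatches = h$mismatches, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(mature_id = character(), family = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$mature_id, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract candidate precursor windows around mature hits
#'
#' For each mature hit and each window length `L`, two windows are proposed:
#' one with the mature anchored near the 5' arm (window extends downstream in
#' mature orientation) and one near the 3' arm (extends upstream). The
#' anchored end keeps a `margin` of sequence beyond the mature, since a
#' mature rarely sits at the very terminus of its precursor (the duplex has
#' a lower stem). Windows are clipped at the locus edges and flagged when
#' clipped. Window sequences are returned as RNA in mature orientation
#' (minus-strand hits are reverse-complemented), with the mature's offsets
#' inside the window.
#'
#' @param hits mature hit data.frame from [scan_matures()]
#' @param locus_seq the scanned sequence record
#' @param window_lens candidate precursor lengths in nt
#'   (default `c(100, 150, 200, 250)`, covering typical plant pre-miRNAs)
#' @param margin nt of sequence kept beyond the mature at its anchored end
#'   (default 10)
#' @return data.frame with columns `mature_id`, `family`, `chrom`, `start`,
#'   `end`, `strand`, `arm` (`"5p"`/`"3p"`), `window_len`, `seq` (RNA),
#'   `mat_from`, `mat_to` (1-based offsets within `seq`), `hit_start`,
#'   `hit_end` (genomic mature anchor), `clipped`
#' @export
extract_candidates <- function(hits, locus_seq,
                               window_lens = c(100L, 150L, 200L, 250L),
                               margin = 10L) {
  sseq <- toupper(locus_seq$seq[[1]])
  slen <- nchar(sseq)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    hs <- hits$start[i]
    he <- hits$end[i]
    strand <- hits$strand[i]
    for (L in window_lens) {
      for (arm in c("5p", "3p")) {
        # genomic window: downstream extension in mature orientation for the
        # 5' arm, upstream for the 3' arm, keeping `margin` nt beyond the
        # mature at the anchored end
        if ((arm == "5p") == (strand == "+")) {
          ws <- hs - margin; we <- ws + L - 1
        } else {
          we <- he + margin; ws <- we - L + 1
        }
        clipped <- ws < 1 || we > slen
        ws <- max(1L, ws); we <- min(slen, as.integer(we))
        if (we - ws + 1 < he - hs + 1) next  # window too short to hold mature
        if (hs < ws || he > we) next          # mature fell outside after clip
        wseq <- substr(sseq, ws, we)
        if (strand == "-") wseq <- revcomp_dna(wseq)
        wlen <- nchar(wseq)
        if (strand == "+") {
          mf <- hs - ws + 1
        } else {
          mf <- we - he + 1
        }
        mt <- mf + (he - hs)
        rows[[length(rows) + 1]] <- data.frame(
          mature_id = hits$mature_id[i], family = hits$family[i],
          chrom = hits$chrom[i], start = ws, end = we, strand = strand,
          arm = arm, window_len = L, seq = dna_to_rna(wseq),
          mat_from = mf, mat_to = mt, hit_start = hs, hit_end = he,
          clipped = clipped, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mature_id = character(), family = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      arm = character(), window_len = integer(),
                      seq = character(), mat_from = integer(),
                      mat_to = integer(), hit_start = integer(),
                      hit_end = integer(), clipped = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Fold RNA sequences into minimum-free-energy secondary structures
#'
#' Thermodynamic folding through the ViennaRNA `RNAfold` program (must be on
#' the PATH). Deterministic for a fixed input and engine version; structures
#' are nested (no pseudoknots) with hairpin loops of at least 3 nt.
#'
#' @param seqs character vector of RNA sequences (ACGUN)
#' @return data.frame with columns `seq`, `structure` (dot-bracket), `mfe`
#'   (kcal/mol)
#' @examples
#' \dontrun{fold_rna("GGGAGGAAAACCUCCC")}
#' @export
fold_rna <- function(seqs) {
  seqs <- toupper(seqs)
  bad <- !grepl("^[ACGUN]+$", seqs)
  if (any(bad)) {
    stop("non-RNA characters in sequence(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (length(seqs) == 0) {
    return(data.frame(seq = character(), structure = character(),
                      mfe = numeric(), stringsAsFactors = FALSE))
  }
  input <- as.vector(rbind(paste0(">s", seq_along(seqs)), seqs))
  out <- suppressWarnings(
    system2("RNAfold", args = c("--noPS"), input = input, stdout = TRUE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
    stop("RNAfold failed (is ViennaRNA installed and on the PATH?)")
  }
  struct_lines <- out[seq(3, length(out), by = 3)]
  m <- regmatches(struct_lines,
                  regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)",
                          struct_lines))
  structure <- vapply(m, function(x) x[2], character(1))
  mfe <- as.numeric(vapply(m, function(x) x[3], character(1)))
  if (anyNA(structure) || any(nchar(structure) != nchar(seqs))) {
    stop("could not parse RNAfold output")
  }
  data.frame(seq = seqs, structure = structure, mfe = mfe,
             stringsAsFactors = FALSE)
}

#' Base-pair partner table of a dot-bracket structure
#'
#' @param structure dot-bracket string (nested, `(`/`)`/`.`)
#' @return integer vector; `partner[i]` is the position paired with `i`, or 0
#' @export
parse_dotbracket <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    stop("invalid dot-bracket characters")
  }
  n <- length(chars)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  partner
}

# hairpin loops: pairs (i, j) with no paired position strictly inside
hairpin_loops <- function(partner) {
  loops <- list()
  for (i in seq_along(partner)) {
    j <- partner[i]
    if (j > i) {
      inside <- if (j - i > 1) partner[(i + 1):(j - 1)] else integer(0)
      if (all(inside == 0)) {
        loops[[length(loops) + 1]] <- c(from = i + 1L, to = j - 1L)
      }
    }
  }
  loops
}

# number of helices emanating directly from the loop closed by pair (i, j)
n_children <- function(partner, i, j) {
  k <- i + 1L
  children <- 0L
  while (k < j) {
    if (partner[k] > k) {
      children <- children + 1L
      k <- partner[k] + 1L
    } else {
      k <- k + 1L
    }
  }
  children
}

#' Evaluate the four hairpin acceptance criteria for precursor candidates
#'
#' Folds each candidate window (unless `structure`/`mfe` columns are already
#' present) and evaluates, per candidate:
#' \describe{
#'   \item{dicer_ok}{no mismatches at the Dicer cut sites — the first and last
#'     `cut_bp` (default 2) bases of the mature are base-paired;}
#'   \item{no_multibranch}{the stem carrying the mature contains no
#'     multi-branched loop (no loop within the mature/star span with more than
#'     one emanating helix);}
#'   \item{not_in_head}{the mature does not overlap the terminal loop of its
#'     hairpin;}
#'   \item{duplex_mismatch_ok}{at most `max_mature_unpaired` (default 4)
#'     unpaired bases within the mature and at most `max_star_unpaired`
#'     (default 6) within the star.}
#' }
#' The star span is inferred from the structure as the positions pairing with
#' the mature, extended by the canonical 2-nt 3' overhang. A candidate is
#' `accepted` iff all four criteria hold.
#'
#' @param cands candidate data.frame from [extract_candidates()] (columns
#'   `seq`, `mat_from`, `mat_to`; `structure` and `mfe` are computed when
#'   absent)
#' @param cut_bp bases checked at each Dicer cut site (default 2)
#' @param max_mature_unpaired,max_star_unpaired duplex mismatch budgets
#' @return `cands` with added columns `structure`, `mfe`, `star_from`,
#'   `star_to`, `dicer_ok`, `no_multibranch`, `not_in_head`,
#'   `duplex_mismatch_ok`, `accepted`
#' @export
evaluate_criteria <- function(cands, cut_bp = 2L, max_mature_unpaired = 4L,
                              max_star_unpaired = 6L) {
  if (nrow(cands) == 0) {
    for (col in c("structure", "star_from", "star_to", "dicer_ok",
                  "no_multibranch", "not_in_head", "duplex_mismatch_ok",
                  "accepted")) cands[[col]] <- vector(
                    if (grepl("ok|branch|head|accepted", col)) "logical"
                    else if (col == "structure") "character" else "integer", 0)
    cands$mfe <- numeric(0)
    return(cands)
  }
  if (is.null(cands$structure)) {
    folded <- fold_rna(cands$seq)
    cands$structure <- folded$structure
    cands$mfe <- folded$mfe
  }
  n <- nrow(cands)
  res <- data.frame(star_from = integer(n), star_to = integer(n),
                    dicer_ok = logical(n), no_multibranch = logical(n),
                    not_in_head = logical(n), duplex_mismatch_ok = logical(n))
  for (i in seq_len(n)) {
    m1 <- cands$mat_from[i]
    m2 <- cands$mat_to[i]
    L <- nchar(cands$seq[i])
    if (m1 < 1 || m2 > L || m1 > m2) {
      stop("mature span [", m1, ", ", m2, "] outside candidate sequence ",
           "of length ", L)
    }
    partner <- parse_dotbracket(cands$structure[i])
    mat <- m1:m2
    pmat <- partner[mat]
    paired <- pmat > 0

    # Dicer cut sites: terminal cut_bp bases at both mature ends paired
    ends <- c(m1:(m1 + cut_bp - 1L), (m2 - cut_bp + 1L):m2)
    res$dicer_ok[i] <- all(partner[ends] > 0)

    if (!any(paired)) {
      res$star_from[i] <- NA_integer_
      res$star_to[i] <- NA_integer_
      res$no_multibranch[i] <- FALSE
      res$not_in_head[i] <- FALSE
      res$duplex_mismatch_ok[i] <- FALSE
      next
    }

    partners <- pmat[paired]
    star_from <- min(partners)
    star_to <- min(max(partners) + 2L, L)  # 2-nt 3' overhang
    res$star_from[i] <- star_from
    res$star_to[i] <- star_to

    # span of the hairpin carrying the mature/star duplex
    span_lo <- min(mat[paired], partners)
    span_hi <- max(mat[paired], partners)

    # multibranch: any loop within the span with >1 emanating helix
    multibranch <- FALSE
    for (p in span_lo:span_hi) {
      q <- partner[p]
      if (q > p && p >= span_lo && q <= span_hi) {
        if (n_children(partner, p, q) >= 2L) {
          multibranch <- TRUE
          break
        }
      }
    }
    res$no_multibranch[i] <- !multibranch

    # head: terminal loop(s) of this hairpin must not overlap the mature
    loops <- hairpin_loops(partner)
    in_head <- FALSE
    for (lp in loops) {
      if (lp["from"] > lp["to"]) next
      if (lp["from"] >= span_lo && lp["to"] <= span_hi &&
          lp["from"] <= m2 && lp["to"] >= m1) {
        in_head <- TRUE
        break
      }
    }
    res$not_in_head[i] <- !in_head

    star_unpaired <- sum(partner[star_from:star_to] == 0)
    res$duplex_mismatch_ok[i] <- sum(!paired) <= max_mature_unpaired &&
      star_unpaired <= max_star_unpaired
  }
  cands <- cbind(cands, res)
  cands$accepted <- res$dicer_ok & res$no_multibranch & res$not_in_head &
    res$duplex_mismatch_ok
  cands
}

#' Collapse overlapping same-family precursor candidates
#'
#' Accepted candidates of the same family whose genomic windows (same
#' chromosome, either strand — the reverse complement of a hairpin is the
#' same hairpin) overlap by at least `min_overlap` of the shorter window, or
#' whose mature anchors lie within `anchor_gap` bp of each other (the mature
#' and star arms of one hairpin), are collapsed to the candidate with the
#' lowest folding energy.
#'
#' @param cands accepted candidate data.frame (rows with `accepted == FALSE`
#'   are dropped)
#' @param min_overlap overlap fraction of the shorter window (default 0.5)
#' @param anchor_gap maximum distance in bp between mature anchors that still
#'   counts as one hairpin (default 100, about one precursor length)
#' @return deduplicated candidate data.frame
#' @export
dedupe_precursors <- function(cands, min_overlap = 0.5, anchor_gap = 100L) {
  cands <- cands[isTRUE_vec(cands$accepted), , drop = FALSE]
  if (nrow(cands) <= 1) {
    rownames(cands) <- NULL
    return(cands)
  }
  o <- order(cands$mfe, cands$start, cands$end, cands$mature_id, cands$arm)
  cands <- cands[o, , drop = FALSE]
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (cands$family[i] != cands$family[j] ||
          cands$chrom[i] != cands$chrom[j]) next
      ov <- min(cands$end[i], cands$end[j]) -
        max(cands$start[i], cands$start[j]) + 1
      shorter <- min(cands$end[i] - cands$start[i],
                     cands$end[j] - cands$start[j]) + 1
      anchor_near <- !is.null(cands$hit_start) &&
        (max(cands$hit_start[i], cands$hit_start[j]) -
           min(cands$hit_end[i], cands$hit_end[j])) <= anchor_gap
      if (ov >= min_overlap * shorter || anchor_near) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  out <- cands[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Summarize miRNA families per genome and their sharing partition
#'
#' Computes, per genome, the set of miRNA families among its accepted
#' precursors, precursor counts per family, and the full sharing partition:
#' for every non-empty subset of genomes, the number of families present in
#' exactly those genomes. Wheat genotypes may be merged into one `"wheat"`
#' set, as comparative Venn figures conventionally do.
#'
#' @param per_genome named list of accepted (deduplicated) candidate
#'   data.frames, or of character vectors of family names
#' @param merge_as optional named list mapping a merged label to the genome
#'   names it absorbs, e.g. `list(wheat = c("chinese_spring", "svevo"))`
#' @return list with `families` (named list of family sets), `counts`
#'   (data.frame genome/family/n_precursors), `partition` (data.frame
#'   `members` ("+"-joined genome labels), `n_families`), and
#'   `total_families`
#' @export
summarize_families <- function(per_genome, merge_as = NULL) {
  fam_sets <- lapply(per_genome, function(x) {
    if (is.data.frame(x)) sort(unique(x$family)) else sort(unique(x))
  })
  counts <- do.call(rbind, lapply(names(per_genome), function(g) {
    x <- per_genome[[g]]
    if (!is.data.frame(x) || nrow(x) == 0) return(NULL)
    tab <- table(x$family)
    data.frame(genome = g, family = names(tab),
               n_precursors = as.integer(tab), stringsAsFactors = FALSE)
  }))
  if (is.null(counts)) {
    counts <- data.frame(genome = character(), family = character(),
                         n_precursors = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(merge_as)) {
    for (lab in names(merge_as)) {
      members <- merge_as[[lab]]
      merged <- sort(unique(unlist(fam_sets[members])))
      fam_sets <- fam_sets[setdiff(names(fam_sets), members)]
      fam_sets[[lab]] <- merged
    }
  }
  genomes <- names(fam_sets)
  all_fams <- sort(unique(unlist(fam_sets)))
  membership <- vapply(genomes, function(g) all_fams %in% fam_sets[[g]],
                       logical(length(all_fams)))
  if (length(all_fams) == 1) membership <- matrix(membership, nrow = 1)
  sig <- apply(membership, 1, function(r)
    paste(genomes[r], collapse = "+"))
  # enumerate every non-empty region of the Venn, including empty regions
  subsets <- unlist(lapply(seq_along(genomes), function(k)
    utils::combn(genomes, k, FUN = function(x)
      paste(x, collapse = "+"), simplify = FALSE)), recursive = FALSE)
  partition <- data.frame(
    members = unlist(subsets),
    n_families = vapply(unlist(subsets), function(s)
      sum(sig == s), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(partition) <- NULL
  list(families = fam_sets, counts = counts, partition = partition,
       total_families = length(all_fams))
}
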