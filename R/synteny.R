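# Cross-genome gene-order comparison: homolog assignment against a reference
# genotype, inversion calling, and plot-table export.

#' Assign each query gene its best reference homolog
#'
#' Hits (query CDS vs reference CDS) are filtered by `preset`; per query gene
#' the best-scoring reference gene is chosen by bitscore, then percent
#' identity, then proximity of the reference gene's rank to the assignments of
#' the query's chromosomal neighbours, then lexicographic reference gene id.
#' One-to-one coloring semantics: each query gene maps to at most one
#' reference gene; genes without a passing hit map to `NA`.
#'
#' @param query_genes,ref_genes locus gene tables from
#'   [extract_locus_genes()] (transcript ids must match the hit table's
#'   `qid`/`sid`)
#' @param hits CDS-vs-CDS hit data.frame
#' @param preset filter preset (name or list), see [homology_preset()]
#' @return data.frame with columns `gene_id`, `rank`, `ref_gene`
#'   (NA when unmatched) and `ref_rank`
#' @export
assign_homologs <- function(query_genes, ref_genes, hits, preset) {
  f <- filter_hits(hits, preset)
  q_gene <- query_genes$gene_id[match(f$qid, query_genes$transcript_id)]
  r_gene <- ref_genes$gene_id[match(f$sid, ref_genes$transcript_id)]
  ok <- !is.na(q_gene) & !is.na(r_gene)
  f <- f[ok, , drop = FALSE]
  q_gene <- q_gene[ok]
  r_gene <- r_gene[ok]
  r_rank <- ref_genes$rank[match(r_gene, ref_genes$gene_id)]

  assigned <- rep(NA_character_, nrow(query_genes))
  names(assigned) <- query_genes$gene_id

  # first pass: genes whose best candidate is unique by (bitscore, pident)
  cand <- split(seq_along(q_gene), q_gene)
  pick_best <- function(idx) {
    o <- idx[order(-f$bitscore[idx], -f$pident[idx])]
    top <- o[abs(f$bitscore[o] - f$bitscore[o[1]]) < 1e-9 &
               abs(f$pident[o] - f$pident[o[1]]) < 1e-9]
    top
  }
  tied <- list()
  for (g in names(cand)) {
    top <- pick_best(cand[[g]])
    if (length(unique(r_gene[top])) == 1) {
      assigned[g] <- r_gene[top[1]]
    } else {
      tied[[g]] <- top
    }
  }
  # second pass: break ties by reference-rank proximity to the neighbours'
  # assignments along the query chromosome
  if (length(tied)) {
    ref_rank_of <- function(gid) {
      ref_genes$rank[match(gid, ref_genes$gene_id)]
    }
    qrank <- query_genes$rank
    names(qrank) <- query_genes$gene_id
    for (g in names(tied)) {
      top <- tied[[g]]
      rk <- qrank[g]
      neigh <- query_genes$gene_id[abs(query_genes$rank - rk) <= 2 &
                                     query_genes$gene_id != g]
      neigh_ranks <- ref_rank_of(assigned[neigh])
      neigh_ranks <- neigh_ranks[!is.na(neigh_ranks)]
      target <- if (length(neigh_ranks)) stats::median(neigh_ranks) else NA
      o <- top[order(if (is.na(target)) rep(0, length(top))
                     else abs(r_rank[top] - target),
                     r_gene[top])]
      assigned[g] <- r_gene[o[1]]
    }
  }

  data.frame(
    gene_id = query_genes$gene_id,
    rank = query_genes$rank,
    ref_gene = unname(assigned[query_genes$gene_id]),
    ref_rank = ref_genes$rank[match(assigned[query_genes$gene_id],
                                    ref_genes$gene_id)],
    stringsAsFactors = FALSE
  )
}

#' Build a synteny map across genomes
#'
#' @param assignments named list of per-genome assignment tables from
#'   [assign_homologs()]; the reference genome itself may be included as the
#'   identity assignment
#' @param reference_genome name of the reference genotype
#' @return object of class `synteny_map`
#' @export
synteny_map <- function(assignments, reference_genome) {
  stopifnot(is.list(assignments), length(names(assignments)) ==
              length(assignments))
  structure(list(reference_genome = reference_genome,
                 assignments = assignments),
            class = "synteny_map")
}

#' @export
print.synteny_map <- function(x, ...) {
  cat("Synteny map vs reference", x$reference_genome, "\n")
  for (g in names(x$assignments)) {
    a <- x$assignments[[g]]
    cat(sprintf("  %s: %d genes, %d mapped\n", g, nrow(a),
                sum(!is.na(a$ref_gene))))
  }
  invisible(x)
}

#' Call candidate inversions from a homolog assignment
#'
#' Reports every maximal run of at least `min_run` consecutive mapped genes
#' whose reference ranks are strictly decreasing. Unmapped genes are skipped
#' (the run is over consecutive *mapped* genes). This operationalizes what
#' comparative figures show by eye; it is a surrogate, not a breakpoint
#' mapper.
#'
#' @param assignment one assignment table from [assign_homologs()], or a
#'   `synteny_map` (then all non-reference genomes are scanned)
#' @param min_run minimum run length in mapped genes (default 4)
#' @param genome label attached to calls when `assignment` is a table
#' @return data.frame with columns `genome`, `rank_from`, `rank_to`, `length`
#'   (number of mapped genes in the run)
#' @export
call_inversions <- function(assignment, min_run = 4L, genome = NA_character_) {
  if (inherits(assignment, "synteny_map")) {
    out <- lapply(setdiff(names(assignment$assignments),
                          assignment$reference_genome), function(g)
      call_inversions(assignment$assignments[[g]], min_run = min_run,
                      genome = g))
    out <- do.call(rbind, out)
    if (is.null(out)) out <- empty_inversions()
    return(out)
  }
  mapped <- assignment[!is.na(assignment$ref_rank), , drop = FALSE]
  mapped <- mapped[order(mapped$rank), , drop = FALSE]
  n <- nrow(mapped)
  if (n < 2) return(empty_inversions())
  dec <- diff(mapped$ref_rank) < 0
  calls <- list()
  i <- 1
  while (i <= length(dec)) {
    if (dec[i]) {
      j <- i
      while (j < length(dec) && dec[j + 1]) j <- j + 1
      run_len <- j - i + 2  # genes, not steps
      if (run_len >= min_run) {
        calls[[length(calls) + 1]] <- data.frame(
          genome = genome, rank_from = mapped$rank[i],
          rank_to = mapped$rank[j + 1], length = run_len,
          stringsAsFactors = FALSE)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(calls)) return(empty_inversions())
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

empty_inversions <- function() {
  data.frame(genome = character(), rank_from = integer(),
             rank_to = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Export a per-gene plot table from a synteny map
#'
#' One row per genome and gene, with the gene's rank along its segment, its
#' homology color key (the assigned reference gene id, `NA` = uncolored) and
#' a highlight flag for user-designated genes (causal or candidate
#' homologs). Reference-genome rows are colored by themselves. Segment
#' lengths in a rendering should be proportional to each genome's gene count,
#' which this table encodes directly.
#'
#' @param map a `synteny_map`
#' @param highlight character vector of gene ids to flag
#' @return data.frame with columns `genome`, `rank`, `gene_id`, `color_key`,
#'   `highlight`
#' @export
export_synteny_plot_data <- function(map, highlight = character()) {
  stopifnot(inherits(map, "synteny_map"))
  rows <- lapply(names(map$assignments), function(g) {
    a <- map$assignments[[g]]
    key <- if (g == map$reference_genome) a$gene_id else a$ref_gene
    data.frame(genome = g, rank = a$rank, gene_id = a$gene_id,
               color_key = key, highlight = a$gene_id %in% highlight,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
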