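# Extracting the gene complement of an inferred locus and choosing each
# gene's longest coding isoform as its representative transcript.

#' Extract locus genes with their longest isoforms
#'
#' Selects the genes of `genes` that intersect the locus interval (any
#' overlap by default; set `mode = "within"` for strict containment), orders
#' them along the chromosome and, per gene, retains only the isoform with the
#' maximal total CDS length (ties broken by lexicographically smaller
#' transcript id). Genes with zero coding isoforms are excluded from the
#' transcript set and counted in the `n_noncoding` attribute.
#'
#' @param genes gene data.frame as from [read_gff_genes()]
#' @param interval one-row interval data.frame (or list) with `chrom`,
#'   `start`, `end`
#' @param cds sequence-record data.frame of coding sequences, ids matching
#'   transcript ids
#' @param mode `"overlap"` (default) or `"within"`
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `transcript_id`, `cds_length`, `cds_seq`, `rank`
#'   (1-based position index along the chromosome). Attribute `n_noncoding`
#'   counts intersecting genes without coding isoforms.
#' @export
extract_locus_genes <- function(genes, interval, cds,
                                mode = c("overlap", "within")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(interval$chrom), interval$start <= interval$end)
  g <- genes[genes$chrom == interval$chrom, , drop = FALSE]
  sel <- if (mode == "overlap") {
    g$start <= interval$end & g$end >= interval$start
  } else {
    g$start >= interval$start & g$end <= interval$end
  }
  g <- g[sel, , drop = FALSE]
  g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]

  n_iso <- vapply(g$isoforms, nrow, integer(1))
  n_noncoding <- sum(n_iso == 0)
  g <- g[n_iso > 0, , drop = FALSE]

  if (nrow(g) == 0) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), transcript_id = character(),
                      cds_length = integer(), cds_seq = character(),
                      rank = integer(), stringsAsFactors = FALSE)
    attr(out, "n_noncoding") <- n_noncoding
    return(out)
  }

  chosen <- vapply(g$isoforms, function(iso) {
    o <- order(-iso$cds_length, iso$transcript_id)
    iso$transcript_id[o[1]]
  }, character(1))
  chosen_len <- vapply(g$isoforms, function(iso) {
    o <- order(-iso$cds_length, iso$transcript_id)
    iso$cds_length[o[1]]
  }, integer(1))

  seq_idx <- match(chosen, cds$id)
  if (anyNA(seq_idx)) {
    stop("CDS sequence missing for transcript(s): ",
         paste(chosen[is.na(seq_idx)], collapse = ", "))
  }

  out <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
    strand = g$strand, transcript_id = chosen, cds_length = chosen_len,
    cds_seq = cds$seq[seq_idx], rank = seq_len(nrow(g)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_noncoding") <- n_noncoding
  out
}

#' Write the chosen CDS of a locus gene table to FASTA
#' @param locus_genes output of [extract_locus_genes()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_locus_cds <- function(locus_genes, path) {
  write_fasta(data.frame(id = locus_genes$transcript_id,
                         description = locus_genes$gene_id,
                         seq = locus_genes$cds_seq,
                         stringsAsFactors = FALSE), path)
}
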