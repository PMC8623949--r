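# End-to-end per-locus workflow: marker filtering -> region inference ->
# gene extraction -> synteny vs a reference genotype -> miRNA discovery ->
# target scoring, with a serialized run report.

#' Run the full locus-comparison pipeline on a simulated or loaded fixture
#'
#' Stages are executed in order per genome: scan the marker panel, filter by
#' the genome's preset and drop ambiguous markers, cluster by continuity,
#' infer the homologous interval, extract locus genes (longest isoform),
#' assign homologs against the reference genotype and call inversions, then
#' scan the locus for mature miRNA matches, fold and filter precursor
#' candidates, summarize families across genomes, and score miRNA targets
#' against the locus coding sequences. Every threshold used is recorded in
#' the report, which alone suffices to reproduce the run.
#'
#' @param sim a `locus_sim` from [simulate_locus_set()] (or an equivalently
#'   shaped list loaded from files)
#' @param reference_genome reference genotype for the synteny comparison
#'   (default: first genome)
#' @param marker_presets named character vector mapping each genome to a
#'   marker preset name (default: `wheat_marker` for the reference,
#'   `rice_marker` for the rest, accommodating the divergence range)
#' @param synteny_preset preset for CDS-vs-CDS homolog assignment
#' @param min_support minimum distinct markers per chromosome for an interval
#' @param max_gap continuity-clustering gap in bp
#' @param min_run minimum mapped-gene run length for inversion calls
#' @param window_lens precursor window lengths
#' @param max_expectation target-score retention cutoff
#' @param out_dir optional directory; when given, interval BED, gene tables,
#'   precursor/target tables and `report.json` are written there
#' @return run report (list), invisibly classed `qtloci_report`
#' @export
run_pipeline <- function(sim,
                         reference_genome = names(sim$genomes)[1],
                         marker_presets = NULL,
                         synteny_preset = "rice_transcript",
                         min_support = 3L,
                         max_gap = 2e6,
                         min_run = 4L,
                         window_lens = c(100L, 150L, 200L, 250L),
                         max_expectation = 3,
                         out_dir = NULL) {
  genomes <- names(sim$genomes)
  stopifnot(reference_genome %in% genomes)
  if (is.null(marker_presets)) {
    marker_presets <- stats::setNames(
      ifelse(genomes == reference_genome, "wheat_marker", "rice_marker"),
      genomes)
  }
  if (nrow(sim$markers) == 0) {
    stop("region inference aborted: the marker panel is empty; ",
         "provide markers or a transcript projection")
  }

  report <- list(
    parameters = list(
      reference_genome = reference_genome,
      marker_presets = as.list(marker_presets),
      synteny_preset = synteny_preset,
      min_support = min_support, max_gap = max_gap, min_run = min_run,
      window_lens = window_lens, max_expectation = max_expectation,
      upe_filter = "disabled (site accessibility not computed)",
      max_mature_mismatch = 1L
    ),
    genomes = list()
  )

  per_genome <- list()
  for (genome in genomes) {
    g <- sim$genomes[[genome]]
    preset <- homology_preset(marker_presets[[genome]])
    max_mm <- floor(nchar(sim$markers$seq) *
                      (1 - preset$min_pident / 100)) + 1L

    hits <- list()
    for (i in seq_len(nrow(sim$markers))) {
      hits[[i]] <- internal_scan(sim$markers[i, ], g$chromosome,
                                 max_mismatch = max_mm[i],
                                 both_strands = TRUE)
    }
    hits <- do.call(rbind, hits)
    n_raw <- nrow(hits)
    hits <- filter_hits(hits, preset)
    n_filtered <- nrow(hits)
    hits <- drop_ambiguous_markers(hits)
    n_unambiguous <- nrow(hits)
    hits <- continuity_filter(hits, max_gap = max_gap)
    interval <- infer_interval(hits, min_support = min_support,
                               genome = genome, method = "marker")
    if (nrow(interval) == 0) {
      stop("region inference failed for ", genome, ": fewer than ",
           min_support, " unambiguous markers on any chromosome ",
           "(", n_unambiguous, " markers retained); consider a looser ",
           "preset or transcript projection")
    }
    interval <- interval[which.max(interval$support), , drop = FALSE]

    locus_genes <- extract_locus_genes(g$genes, interval, g$cds)

    per_genome[[genome]] <- list(
      hits = hits, interval = interval, locus_genes = locus_genes,
      counts = list(markers_total = nrow(sim$markers),
                    hits_raw = n_raw, hits_filtered = n_filtered,
                    markers_retained = n_unambiguous,
                    interval = unclass(interval[1, ]),
                    n_genes = nrow(locus_genes))
    )
  }

  # synteny vs reference
  ref <- per_genome[[reference_genome]]$locus_genes
  assignments <- list()
  for (genome in genomes) {
    lg <- per_genome[[genome]]$locus_genes
    if (genome == reference_genome) {
      assignments[[genome]] <- data.frame(
        gene_id = ref$gene_id, rank = ref$rank, ref_gene = ref$gene_id,
        ref_rank = ref$rank, stringsAsFactors = FALSE)
      next
    }
    qcds <- data.frame(id = lg$transcript_id, seq = lg$cds_seq,
                       stringsAsFactors = FALSE)
    rcds <- data.frame(id = ref$transcript_id, seq = ref$cds_seq,
                       stringsAsFactors = FALSE)
    hits <- cds_homology_hits(qcds, rcds, min_pident = 50)
    assignments[[genome]] <- assign_homologs(lg, ref, hits,
                                             preset = synteny_preset)
  }
  map <- synteny_map(assignments, reference_genome)
  inversions <- call_inversions(map, min_run = min_run)

  # miRNA discovery inside each inferred interval
  accepted_by_genome <- list()
  target_rows <- list()
  for (genome in genomes) {
    pg <- per_genome[[genome]]
    g <- sim$genomes[[genome]]
    iv <- pg$interval
    locus_seq <- data.frame(
      id = iv$chrom,
      seq = substr(g$chromosome$seq, iv$start, iv$end),
      stringsAsFactors = FALSE)
    mhits <- scan_matures(locus_seq, sim$matures, max_mismatch = 1L)
    cands <- extract_candidates(mhits, locus_seq, window_lens = window_lens)
    cands <- evaluate_criteria(cands)
    acc <- dedupe_precursors(cands)
    if (nrow(acc)) {
      # shift window coordinates back to chromosome space
      acc$start <- acc$start + iv$start - 1L
      acc$end <- acc$end + iv$start - 1L
      acc$hit_start <- acc$hit_start + iv$start - 1L
      acc$hit_end <- acc$hit_end + iv$start - 1L
    }
    accepted_by_genome[[genome]] <- acc
    per_genome[[genome]]$counts$mature_hits <- nrow(mhits)
    per_genome[[genome]]$counts$candidates <- nrow(cands)
    per_genome[[genome]]$counts$precursors <- nrow(acc)
    per_genome[[genome]]$precursors <- acc

    if (nrow(acc)) {
      fam_matures <- sim$matures[sim$matures$id %in% acc$mature_id, ,
                                 drop = FALSE]
      cds_records <- data.frame(id = pg$locus_genes$transcript_id,
                                seq = pg$locus_genes$cds_seq,
                                stringsAsFactors = FALSE)
      tp <- score_targets(fam_matures, cds_records,
                          max_expectation = max_expectation)
      if (nrow(tp)) tp <- cbind(genome = genome, tp)
      target_rows[[genome]] <- tp
    }
  }
  families <- summarize_families(accepted_by_genome)
  targets <- if (length(target_rows)) {
    do.call(rbind, target_rows)
  } else {
    data.frame(genome = character(), mature_id = character(),
               transcript_id = character(), site_start = integer(),
               site_end = integer(), expectation = numeric(),
               retained = logical(), stringsAsFactors = FALSE)
  }
  rownames(targets) <- NULL

  report$genomes <- lapply(per_genome, `[[`, "counts")
  report$synteny <- list(
    mapped = vapply(assignments, function(a)
      sum(!is.na(a$ref_gene)), integer(1)),
    inversions = inversions
  )
  report$mirna <- list(
    precursors_total = sum(vapply(accepted_by_genome, nrow, integer(1))),
    families_total = families$total_families,
    partition = families$partition,
    targets_retained = sum(targets$retained)
  )

  result <- list(report = report, per_genome = per_genome, map = map,
                 inversions = inversions, families = families,
                 targets = targets)
  class(result) <- "qtloci_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ivs <- do.call(rbind, lapply(per_genome, `[[`, "interval"))
    write_intervals_bed(ivs, file.path(out_dir, "intervals.bed"))
    for (genome in genomes) {
      lg <- per_genome[[genome]]$locus_genes
      utils::write.table(
        lg[, setdiff(names(lg), "cds_seq")],
        file.path(out_dir, paste0(genome, ".genes.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      acc <- per_genome[[genome]]$precursors
      if (nrow(acc)) {
        utils::write.table(
          acc[, setdiff(names(acc), "seq")],
          file.path(out_dir, paste0(genome, ".precursors.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    utils::write.table(export_synteny_plot_data(map),
                       file.path(out_dir, "synteny_plot.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(targets, file.path(out_dir, "targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  invisible(result)
}

#' @export
print.qtloci_run <- function(x, ...) {
  r <- x$report
  cat("qtloci run vs reference", r$parameters$reference_genome, "\n")
  for (g in names(r$genomes)) {
    cnt <- r$genomes[[g]]
    cat(sprintf(
      "  %s: %d/%d markers retained; locus %s:%d-%d; %d genes; %d precursors\n",
      g, cnt$markers_retained, cnt$markers_total, cnt$interval$chrom,
      cnt$interval$start, cnt$interval$end, cnt$n_genes, cnt$precursors))
  }
  cat(sprintf("  inversions called: %d; miRNA families: %d; targets: %d\n",
              nrow(x$inversions), r$mirna$families_total,
              r$mirna$targets_retained))
  invisible(x)
}
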