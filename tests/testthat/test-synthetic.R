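# The synthetic locus generator: determinism, internal consistency and the
# divergence behaviour the scaled filter presets rely on.

small_cfg <- function(seed, ...) {
  simulation_config(
    seed = seed, genomes = c("ref", "rel"), divergence = c(0, 0.02),
    genes_per_locus = 10, n_markers = 8, marker_length = c(60L, 120L),
    intergenic_length = c(300L, 800L), flank_length = 1500L,
    hairpins = data.frame(family = character(), violate = character(),
                          stringsAsFactors = FALSE),
    ...)
}

test_that("the same seed yields byte-identical fixtures", {
  sim1 <- simulate_locus_set(small_cfg(123))
  sim2 <- simulate_locus_set(small_cfg(123))
  expect_identical(sim1, sim2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(sim1, d1)
  write_fixture(sim2, d2)
  for (f in list.files(d1)) {
    if (f == "truth.json") next  # dates differ only in gff headers, not json
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # a different seed changes the sequences
  sim3 <- simulate_locus_set(small_cfg(124))
  expect_false(identical(sim1$genomes$ref$chromosome$seq,
                         sim3$genomes$ref$chromosome$seq))
})

test_that("emitted FASTA/GFF3 cross-validate through the readers", {
  sim <- simulate_locus_set(small_cfg(321))
  d <- withr::local_tempdir()
  write_fixture(sim, d)
  for (g in c("ref", "rel")) {
    chrom <- read_fasta(file.path(d, paste0(g, ".fa")), "dna")
    genes <- read_gff_genes(file.path(d, paste0(g, ".gff3")))
    cds <- read_fasta(file.path(d, paste0(g, ".cds.fa")), "dna")
    # every isoform's CDS id is present, with matching length
    for (i in seq_len(nrow(genes))) {
      iso <- genes$isoforms[[i]]
      expect_true(all(iso$transcript_id %in% cds$id))
      expect_equal(nchar(cds$seq[match(iso$transcript_id, cds$id)]),
                   iso$cds_length)
      expect_true(genes$start[i] >= 1 &&
                    genes$end[i] <= nchar(chrom$seq))
    }
    # in-memory tables agree with what round-trips through disk
    expect_equal(genes[, c("gene_id", "chrom", "start", "end", "strand")],
                 sim$genomes[[g]]$genes[, c("gene_id", "chrom", "start",
                                            "end", "strand")],
                 ignore_attr = TRUE)
  }
  # planted markers sit where the truth says, up to divergence
  tm <- sim$truth$markers
  ref_chrom <- sim$genomes$ref$chromosome$seq
  for (i in which(tm$genome == "ref")) {
    window <- substr(ref_chrom, tm$start[i], tm$end[i])
    mseq <- sim$markers$seq[sim$markers$id == tm$marker_id[i]]
    if (tm$strand[i] == "-") mseq <- rc_dna(mseq)
    expect_equal(window, mseq)
  }
})

test_that("marker recovery degrades with divergence as the presets expect", {
  cfg2 <- simulation_config(
    seed = 99, genomes = c("ref", "near", "far"),
    divergence = c(0, 0.02, 0.10),
    genes_per_locus = 10, n_markers = 10, marker_length = c(80L, 120L),
    intergenic_length = c(300L, 800L), flank_length = 1500L,
    hairpins = data.frame(family = character(), violate = character(),
                          stringsAsFactors = FALSE))
  sim <- simulate_locus_set(cfg2)
  retained <- function(genome, preset) {
    mm <- floor(nchar(sim$markers$seq) * 0.25)
    hits <- do.call(rbind, lapply(seq_len(nrow(sim$markers)), function(i)
      internal_scan(sim$markers[i, ], sim$genomes[[genome]]$chromosome,
                    max_mismatch = mm[i])))
    length(unique(filter_hits(hits, preset)$qid))
  }
  # at 2% divergence the wheat preset (95% identity) keeps most markers
  expect_gte(retained("near", "wheat_marker"), 8)
  # at 10% divergence the wheat preset collapses but the rice preset (80%)
  # still recovers the panel: the evolutionary-distance rationale for
  # species-scaled thresholds
  expect_lte(retained("far", "wheat_marker"), 2)
  expect_gte(retained("far", "rice_marker"), 8)
})

test_that("structural events edit the locus as configured", {
  cfg <- small_cfg(17)
  cfg$events <- list(list(genome = "rel", type = "gene_loss", genes = 4L),
                     list(genome = "rel", type = "inversion", genes = 6:9))
  sim <- simulate_locus_set(cfg)
  to <- sim$truth$orthologs
  ref_idx <- to$gene_index[to$genome == "ref"]
  rel <- to[to$genome == "rel", ]
  expect_false(4L %in% rel$gene_index)
  expect_true(all(setdiff(ref_idx, 4L) %in% rel$gene_index))
  # inverted genes flip strand and reverse their order along the chromosome
  inv <- rel[rel$gene_index %in% 6:9, ]
  inv <- inv[order(inv$start), ]
  expect_equal(inv$gene_index, 9:6)
  expect_true(all(inv$strand == "-"))
})

test_that("hairpin truth records planted coordinates exactly", {
  cfg <- simulation_config(
    seed = 31, genomes = "solo", divergence = 0, genes_per_locus = 8,
    n_markers = 5, intergenic_length = c(300L, 800L), flank_length = 1500L,
    hairpins = data.frame(family = c("miR9201", "miR9202"),
                          violate = c("none", "head"),
                          stringsAsFactors = FALSE))
  sim <- simulate_locus_set(cfg)
  th <- sim$truth$hairpins
  chrom <- sim$genomes$solo$chromosome$seq
  for (i in seq_len(nrow(th))) {
    mat <- sim$matures$seq[sim$matures$id == th$mature_id[i]]
    expect_equal(substr(chrom, th$mat_from[i], th$mat_to[i]),
                 chartr("U", "T", mat))
  }
})
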