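# Synthetic multi-genome locus generator with full ground truth.
#
# An ancestral locus (alternating intergenic and gene segments) is generated
# once, then per-genome copies are derived by i.i.d. substitutions (2:1
# transition bias), planted structural events (inversion, translocation, gene
# loss) and post-divergence hairpin insertions. All coordinates in the ground
# truth are recomputed from the assembled segment layout, so emitted
# FASTA/GFF3 and the truth tables stay consistent by construction.

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale multi-genome locus study: four genomes (one
#' undiverged reference plus relatives at increasing evolutionary distance),
#' 20 genes of 300-1200 nt with 1-3 isoforms each, a 12-marker panel of
#' 60-200 nt probes, and a set of planted miRNA hairpins engineered to pass
#' all four acceptance criteria or to violate exactly one.
#'
#' @param seed mandatory RNG seed; the same seed yields byte-identical output
#' @param genomes character vector of genome names; the first is the
#'   undiverged reference
#' @param divergence per-genome substitution rate per site (same length as
#'   `genomes`, each in \[0, 0.3\])
#' @param genes_per_locus number of ancestral genes
#' @param gene_length,intergenic_length uniform length bounds in nt
#' @param max_isoforms maximum isoforms per gene (1-3)
#' @param n_markers,marker_length marker panel size and length bounds
#' @param events list of structural events, each a list with `genome`,
#'   `type` (`"inversion"`, `"translocation"`, `"gene_loss"`) and `genes`
#'   (ancestral gene indices, contiguous for inversion/translocation)
#' @param hairpins data.frame with columns `family` (e.g. `"miR9101"`),
#'   `violate` (`"none"`, `"dicer"`, `"multibranch"`, `"head"`, `"duplex"`)
#'   and optionally `genomes` ("+"-joined genome names; default all genomes)
#' @param plant_target embed a perfect reverse-complement target site of the
#'   first clean planted mature into the coding region of a mid-locus gene,
#'   so target scoring has a known positive (default TRUE)
#' @param flank_length random flanking sequence on each side of the locus
#' @return object of class `sim_config`
#' @export
simulation_config <- function(seed,
                              genomes = c("genomeA", "genomeB", "genomeC",
                                          "genomeD"),
                              divergence = c(0, 0.02, 0.05, 0.08),
                              genes_per_locus = 20L,
                              gene_length = c(300L, 1200L),
                              intergenic_length = c(400L, 1500L),
                              max_isoforms = 3L,
                              n_markers = 12L,
                              marker_length = c(60L, 200L),
                              events = list(),
                              hairpins = default_hairpin_plan(),
                              plant_target = TRUE,
                              flank_length = 3000L) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(length(genomes) == length(divergence),
            all(divergence >= 0), all(divergence <= 0.3),
            genes_per_locus >= 2, max_isoforms >= 1, max_isoforms <= 3)
  for (ev in events) {
    stopifnot(ev$genome %in% genomes,
              ev$type %in% c("inversion", "translocation", "gene_loss"),
              all(ev$genes >= 1), all(ev$genes <= genes_per_locus))
  }
  structure(list(seed = as.integer(seed), genomes = genomes,
                 divergence = divergence, genes_per_locus = genes_per_locus,
                 gene_length = gene_length,
                 intergenic_length = intergenic_length,
                 max_isoforms = max_isoforms, n_markers = n_markers,
                 marker_length = marker_length, events = events,
                 hairpins = hairpins, plant_target = plant_target,
                 flank_length = flank_length),
            class = "sim_config")
}

#' Default hairpin planting plan: five clean precursors plus one decoy per
#' criterion
#' @return data.frame with columns `family`, `violate`
#' @export
default_hairpin_plan <- function() {
  data.frame(
    family = paste0("miR", 9101:9109),
    violate = c(rep("none", 5), "dicer", "multibranch", "head", "duplex"),
    stringsAsFactors = FALSE
  )
}

#' Generate a random mature miRNA sequence
#'
#' @param len mature length in nt (20-22)
#' @param head_foldback when TRUE the mature is built to fold back on itself
#'   (its 5' and 3' thirds are reverse complements), the construction used for
#'   terminal-loop decoys
#' @return RNA string
#' @export
random_mature <- function(len = 21L, head_foldback = FALSE) {
  stopifnot(len >= 20, len <= 22)
  if (!head_foldback) {
    return(dna_to_rna(random_dna(len)))
  }
  arm <- (len - 3L) %/% 2L
  a <- random_dna(arm)
  mid <- random_dna(len - 2L * arm)
  dna_to_rna(paste0(a, mid, revcomp_dna(a)))
}

# scaffolding constants for hairpin construction; loop is A/C-only so it
# cannot pair with itself, stemlets are GC-rich so they fold reliably
HAIRPIN_FLANK <- "GCGGAUGC"
HAIRPIN_LOOP <- "ACACAACA"
STEMLET_1 <- c("GGCCAGC", "AAAA", "GCUGGCC")
STEMLET_2 <- c("GGUGCUG", "AAAA", "CAGCACC")

nonpairing_base <- function(b) {
  # a base that can form neither a Watson-Crick nor a G:U pair with b
  c(A = "C", C = "A", G = "A", U = "C")[[b]]
}

#' Construct a precursor hairpin for a mature miRNA
#'
#' Builds an inverted-repeat precursor carrying the mature on its 5' arm.
#' With `violate = "none"` the construct passes all four hairpin criteria;
#' otherwise the construction breaks exactly the requested criterion:
#' `"dicer"` unpairs the first two mature bases, `"multibranch"` replaces the
#' terminal loop with two GC-rich stemlets, `"head"` folds the mature back on
#' itself so it overlaps the terminal loop (requires a mature from
#' `random_mature(head_foldback = TRUE)`), and `"duplex"` introduces five
#' bulged bases opposite the mature.
#'
#' @param mature RNA string of 20-22 nt
#' @param violate `"none"`, `"dicer"`, `"multibranch"`, `"head"` or
#'   `"duplex"`
#' @param verify fold the construct and confirm it produces exactly the
#'   intended criterion profile (default TRUE); the duplex decoy escalates
#'   its mutation count until folding confirms more than four unpaired
#'   mature bases. An unverifiable construction is an error.
#' @return list with `seq` (RNA precursor), `mat_from`, `mat_to` (mature
#'   offsets within `seq`), `mature`, `violate`
#' @export
make_hairpin <- function(mature, violate = c("none", "dicer", "multibranch",
                                             "head", "duplex"),
                         verify = TRUE) {
  violate <- match.arg(violate)
  mature <- dna_to_rna(toupper(mature))
  L <- nchar(mature)
  if (L < 20 || L > 22) stop("mature must be 20-22 nt")
  mchars <- strsplit(mature, "", fixed = TRUE)[[1]]

  build <- function(star_mut) {
    if (violate == "head") {
      arm <- (L - 3L) %/% 2L
      if (substr(mature, 1, arm) !=
          revcomp_rna(substr(mature, L - arm + 1, L))) {
        stop("a 'head' decoy needs a fold-back mature ",
             "(see random_mature(head_foldback = TRUE))")
      }
      flank <- "GCGGAUGCGG"
      seq <- paste0(flank, mature, revcomp_rna(flank), "AA")
      return(list(seq = seq, mat_from = nchar(flank) + 1L,
                  mat_to = nchar(flank) + L, mature = mature,
                  violate = violate))
    }
    star <- strsplit(revcomp_rna(mature), "", fixed = TRUE)[[1]]
    # star[k] pairs mature position L + 1 - k
    if (violate == "duplex") {
      # delete star bases opposite the mature interior: the rest of the
      # duplex stays perfectly complementary, forcing a bulge on the mature
      # arm (>4 unpaired mature bases) without destabilizing the hairpin
      star <- star[-(L + 1L - star_mut)]
    } else {
      for (p in star_mut) {
        star[L + 1L - p] <- nonpairing_base(mchars[p])
      }
    }
    loop <- HAIRPIN_LOOP
    if (violate == "multibranch") {
      loop <- paste0("A", paste(STEMLET_1, collapse = ""), "AA",
                     paste(STEMLET_2, collapse = ""), "A")
    }
    seq <- paste0(HAIRPIN_FLANK, mature, loop, paste(star, collapse = ""),
                  revcomp_rna(HAIRPIN_FLANK), "AA")
    list(seq = seq, mat_from = nchar(HAIRPIN_FLANK) + 1L,
         mat_to = nchar(HAIRPIN_FLANK) + L, mature = mature,
         violate = violate)
  }

  # star modifications per decoy type; the duplex ladder deepens the star
  # deletion if the folding engine ever rescues pairs from flanking sequence
  mut_sets <- switch(violate,
    none = list(integer(0)),
    head = list(integer(0)),
    dicer = list(c(1L, 2L)),
    multibranch = list(integer(0)),
    duplex = list(8:12, 7:13)
  )
  intended <- c(dicer_ok = TRUE, no_multibranch = TRUE, not_in_head = TRUE,
                duplex_mismatch_ok = TRUE)
  if (violate != "none") {
    intended[[c(dicer = "dicer_ok", multibranch = "no_multibranch",
                head = "not_in_head", duplex = "duplex_mismatch_ok")[[violate]]]] <- FALSE
  }
  for (ms in mut_sets) {
    h <- build(ms)
    if (!verify) return(h)
    ev <- evaluate_criteria(data.frame(seq = h$seq, mat_from = h$mat_from,
                                       mat_to = h$mat_to,
                                       stringsAsFactors = FALSE))
    got <- c(dicer_ok = ev$dicer_ok, no_multibranch = ev$no_multibranch,
             not_in_head = ev$not_in_head,
             duplex_mismatch_ok = ev$duplex_mismatch_ok)
    if (identical(unname(got), unname(intended))) return(h)
  }
  stop("could not construct a '", violate, "' hairpin for mature ", mature,
       " with the intended criterion profile")
}

# --- internal: segment machinery -------------------------------------------

# ancestral locus: list of segments; each segment is a list with
#   type ("intergenic" | "gene"), id, seq, and for genes the isoform table
#   (transcript_id, exon list of local [from, to]) in gene-local plus-strand
#   coordinates
build_ancestral <- function(cfg) {
  segs <- list()
  add <- function(s) segs[[length(segs) + 1]] <<- s
  ig_len <- function() sample(cfg$intergenic_length[1]:
                                cfg$intergenic_length[2], 1)
  add(list(type = "intergenic", id = "ig0", seq = random_dna(ig_len())))
  for (k in seq_len(cfg$genes_per_locus)) {
    glen <- sample(cfg$gene_length[1]:cfg$gene_length[2], 1)
    n_iso <- sample(seq_len(cfg$max_isoforms), 1)
    isoforms <- lapply(seq_len(n_iso), function(j) {
      if (stats::runif(1) < 0.5 || glen < 240) {
        # single-exon isoform: a prefix of the gene
        l <- sample(seq(max(60, glen %/% 2), glen, by = 1), 1)
        exons <- list(c(1L, as.integer(l)))
      } else {
        # two-exon isoform with an internal intron
        e1 <- sample(60:(glen %/% 3), 1)
        intron <- sample(30:(glen %/% 3), 1)
        exons <- list(c(1L, as.integer(e1)),
                      c(as.integer(e1 + intron + 1L), as.integer(glen)))
      }
      list(transcript_id = sprintf("anc_g%02d.t%d", k, j), exons = exons)
    })
    add(list(type = "gene", id = sprintf("anc_g%02d", k),
             gene_index = k, seq = random_dna(glen), isoforms = isoforms))
    add(list(type = "intergenic", id = sprintf("ig%d", k),
             seq = random_dna(ig_len())))
  }
  segs
}

# substitutions with 2:1 transition bias
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  for (i in hit) {
    b <- chars[i]
    if (!b %in% names(transitions)) next
    if (stats::runif(1) < 2 / 3) {
      chars[i] <- transitions[[b]]
    } else {
      chars[i] <- sample(transversions[[b]], 1)
    }
  }
  paste(chars, collapse = "")
}

seg_gene_indices <- function(segs) {
  vapply(segs, function(s)
    if (s$type == "gene") s$gene_index else NA_integer_, integer(1))
}

# apply one structural event to a segment list; segments carry a `flipped`
# flag used to orient genes and anchored features afterwards
apply_event <- function(segs, ev) {
  gi <- seg_gene_indices(segs)
  if (ev$type == "gene_loss") {
    for (g in ev$genes) {
      k <- which(gi == g)
      if (!length(k)) next
      # drop the gene and the intergenic segment after it
      drop <- k
      if (k < length(segs) && segs[[k + 1]]$type == "intergenic") {
        drop <- c(k, k + 1)
      }
      segs <- segs[-drop]
      gi <- seg_gene_indices(segs)
    }
    return(segs)
  }
  gs <- sort(ev$genes)
  if (!all(diff(gs) == 1)) stop("event genes must be contiguous")
  k1 <- which(gi == gs[1])
  k2 <- which(gi == gs[length(gs)])
  if (!length(k1) || !length(k2)) stop("event genes missing from locus")
  block <- segs[k1:k2]
  if (ev$type == "inversion") {
    block <- rev(lapply(block, function(s) {
      s$seq <- revcomp_dna(s$seq)
      s$flipped <- !isTRUE(s$flipped)
      s
    }))
    segs[k1:k2] <- block
    return(segs)
  }
  # translocation: move the block (with one flanking intergenic) to the
  # locus end, after the final intergenic segment
  rest <- segs[-(k1:k2)]
  c(rest, block)
}

# assemble a segment list into a chromosome: returns seq, a segment layout
# table and per-gene annotation rows
assemble_genome <- function(segs, genome, chrom, flank_length) {
  left <- random_dna(flank_length)
  right <- random_dna(flank_length)
  seqs <- vapply(segs, `[[`, character(1), "seq")
  lens <- nchar(seqs)
  starts <- flank_length + cumsum(c(0L, utils::head(lens, -1))) + 1L
  ends <- starts + lens - 1L
  layout <- data.frame(
    seg_id = vapply(segs, `[[`, character(1), "id"),
    type = vapply(segs, `[[`, character(1), "type"),
    gene_index = seg_gene_indices(segs),
    start = starts, end = ends,
    flipped = vapply(segs, function(s) isTRUE(s$flipped), logical(1)),
    stringsAsFactors = FALSE
  )
  chrom_seq <- paste0(left, paste(seqs, collapse = ""), right)
  list(chrom = chrom, seq = chrom_seq, layout = layout,
       locus_start = flank_length + 1L,
       locus_end = flank_length + sum(lens))
}

# gene/isoform annotation + CDS sequences for one assembled genome
annotate_genome <- function(segs, asm, genome) {
  layout <- asm$layout
  genes <- list()
  cds <- list()
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    if (s$type != "gene") next
    gstart <- layout$start[k]
    gend <- layout$end[k]
    glen <- gend - gstart + 1L
    strand <- if (isTRUE(s$flipped)) "-" else "+"
    gene_id <- sprintf("%s_g%02d", genome, s$gene_index)
    iso_rows <- list()
    for (iso in s$isoforms) {
      tx_id <- sprintf("%s_g%02d.t%s", genome, s$gene_index,
                       sub("^.*\\.t", "", iso$transcript_id))
      # exon coordinates in chromosome space; for flipped genes the local
      # plus-strand coordinates count from the gene's other end
      exons_chrom <- lapply(iso$exons, function(e) {
        if (strand == "+") {
          c(gstart + e[1] - 1L, gstart + e[2] - 1L)
        } else {
          c(gend - e[2] + 1L, gend - e[1] + 1L)
        }
      })
      exons_chrom <- exons_chrom[order(vapply(exons_chrom,
                                              function(e) e[1], integer(1)))]
      cds_len <- sum(vapply(iso$exons, function(e) e[2] - e[1] + 1L,
                            integer(1)))
      # spliced CDS in transcript orientation
      pieces <- vapply(iso$exons, function(e) {
        # e is in transcript-local plus coordinates of the (possibly
        # flipped) gene sequence as laid out on the chromosome
        if (strand == "+") {
          substr(asm$seq, gstart + e[1] - 1L, gstart + e[2] - 1L)
        } else {
          revcomp_dna(substr(asm$seq, gend - e[2] + 1L, gend - e[1] + 1L))
        }
      }, character(1))
      cds[[length(cds) + 1]] <- data.frame(
        id = tx_id, description = gene_id,
        seq = paste(pieces, collapse = ""), stringsAsFactors = FALSE)
      iso_rows[[length(iso_rows) + 1]] <- list(
        transcript_id = tx_id, cds_length = as.integer(cds_len),
        exons_chrom = exons_chrom)
    }
    genes[[length(genes) + 1]] <- list(
      gene_id = gene_id, gene_index = s$gene_index, chrom = asm$chrom,
      start = gstart, end = gend, strand = strand, isoforms = iso_rows)
  }
  list(genes = genes, cds = do.call(rbind, cds))
}

genes_to_df <- function(genes) {
  df <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    start = vapply(genes, `[[`, integer(1), "start"),
    end = vapply(genes, `[[`, integer(1), "end"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE
  )
  df$isoforms <- lapply(genes, function(g) {
    data.frame(
      transcript_id = vapply(g$isoforms, `[[`, character(1),
                             "transcript_id"),
      cds_length = vapply(g$isoforms, `[[`, integer(1), "cds_length"),
      stringsAsFactors = FALSE)
  })
  o <- order(df$start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Simulate a multi-genome locus set with ground truth
#'
#' See [simulation_config()] for the tunable study conditions. Markers are
#' subsequences of ancestral genes, so each genome's copy diverges with that
#' genome's substitution rate; hairpins are inserted after divergence so the
#' planted mature always matches the reference set exactly.
#'
#' @param cfg a `sim_config`
#' @return list of class `locus_sim` with elements `genomes` (per genome:
#'   `chromosome` sequence record, `genes` table, `cds` records, `layout`),
#'   `markers`, `matures` (sequence-record data.frames) and `truth` (locus
#'   borders, ortholog table, marker positions, hairpin plantings, events)
#' @export
simulate_locus_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    anc <- build_ancestral(cfg)
    gene_segs <- which(vapply(anc, `[[`, character(1), "type") == "gene")

    # hairpin plan: matures + precursor constructs (shared across genomes)
    hp <- cfg$hairpins
    if (is.null(hp$genomes)) {
      hp$genomes <- rep(paste(cfg$genomes, collapse = "+"), nrow(hp))
    }
    hp_constructs <- lapply(seq_len(nrow(hp)), function(i) {
      mat <- random_mature(21L, head_foldback = hp$violate[i] == "head")
      h <- make_hairpin(mat, violate = hp$violate[i])
      h$family <- hp$family[i]
      h$mature_id <- sprintf("syn-%sa", sub("^miR", "miR", hp$family[i]))
      h$genomes <- strsplit(hp$genomes[i], "+", fixed = TRUE)[[1]]
      h
    })
    matures <- data.frame(
      id = vapply(hp_constructs, `[[`, character(1), "mature_id"),
      description = rep("synthetic mature miRNA", length(hp_constructs)),
      seq = vapply(hp_constructs, `[[`, character(1), "mature"),
      stringsAsFactors = FALSE
    )

    # plant a perfect target site of the first clean mature into the coding
    # start of a mid-locus gene (within every isoform's first exon)
    target_truth <- NULL
    clean <- which(hp$violate == "none")
    if (isTRUE(cfg$plant_target) && length(clean)) {
      tgt_gene <- ceiling(cfg$genes_per_locus / 2)
      k <- gene_segs[tgt_gene]
      site <- revcomp_dna(rna_to_dna(hp_constructs[[clean[1]]]$mature))
      off <- 30L
      anc[[k]]$seq <- paste0(substr(anc[[k]]$seq, 1, off - 1L), site,
                             substr(anc[[k]]$seq, off + nchar(site),
                                    nchar(anc[[k]]$seq)))
      target_truth <- data.frame(
        mature_id = hp_constructs[[clean[1]]]$mature_id,
        gene_index = tgt_gene, cds_offset = off,
        stringsAsFactors = FALSE)
    }

    # marker panel: subsequences of ancestral genes at known anchors (drawn
    # after target planting so every marker matches the reference exactly)
    marker_anchor <- data.frame(
      marker_id = sprintf("marker%02d", seq_len(cfg$n_markers)),
      seg = sample(gene_segs, cfg$n_markers, replace = TRUE),
      stringsAsFactors = FALSE
    )
    marker_anchor$len <- vapply(marker_anchor$seg, function(k) {
      min(sample(cfg$marker_length[1]:cfg$marker_length[2], 1),
          nchar(anc[[k]]$seq))
    }, integer(1))
    marker_anchor$offset <- vapply(seq_len(cfg$n_markers), function(i) {
      k <- marker_anchor$seg[i]
      sample(seq_len(nchar(anc[[k]]$seq) - marker_anchor$len[i] + 1L), 1)
    }, integer(1))
    markers <- data.frame(
      id = marker_anchor$marker_id, description = "synthetic marker",
      seq = vapply(seq_len(cfg$n_markers), function(i) {
        k <- marker_anchor$seg[i]
        substr(anc[[k]]$seq, marker_anchor$offset[i],
               marker_anchor$offset[i] + marker_anchor$len[i] - 1L)
      }, character(1)),
      stringsAsFactors = FALSE
    )

    genomes_out <- list()
    truth_genes <- list()
    truth_markers <- list()
    truth_hairpins <- list()
    truth_borders <- list()

    for (gidx in seq_along(cfg$genomes)) {
      genome <- cfg$genomes[gidx]
      rate <- cfg$divergence[gidx]
      segs <- lapply(anc, function(s) {
        s$seq <- mutate_seq(s$seq, rate)
        s
      })
      for (ev in cfg$events) {
        if (ev$genome == genome) segs <- apply_event(segs, ev)
      }

      # insert hairpins into distinct intergenic segments (post-divergence,
      # fixed slice replacement so coordinates stay deterministic)
      ig_idx <- which(vapply(segs, `[[`, character(1), "type") ==
                        "intergenic")
      ig_pool <- ig_idx[-1]  # keep the first intergenic hairpin-free
      hp_here <- Filter(function(h) genome %in% h$genomes, hp_constructs)
      stopifnot(length(ig_pool) >= length(hp_here))
      # spread plantings across the central part of the locus so they fall
      # inside the marker-delineated interval
      slots <- if (length(hp_here)) {
        unique(ig_pool[pmax(1L, round(seq(0.2, 0.8,
                                          length.out = length(hp_here)) *
                                        length(ig_pool)))])
      } else integer(0)
      if (length(slots) < length(hp_here)) {
        slots <- ig_pool[seq_along(hp_here)]
      }
      hp_offset <- integer(length(hp_here))
      for (j in seq_along(hp_here)) {
        k <- slots[j]
        hseq <- rna_to_dna(hp_here[[j]]$seq)
        off <- 50L
        stopifnot(nchar(segs[[k]]$seq) >= off + nchar(hseq) + 50L)
        segs[[k]]$seq <- paste0(
          substr(segs[[k]]$seq, 1, off),
          hseq,
          substr(segs[[k]]$seq, off + nchar(hseq) + 1L,
                 nchar(segs[[k]]$seq)))
        hp_offset[j] <- off + 1L
        segs[[k]]$hairpin <- j
      }

      chrom <- paste0("chr1_", genome)
      asm <- assemble_genome(segs, genome, chrom, cfg$flank_length)
      ann <- annotate_genome(segs, asm, genome)

      genomes_out[[genome]] <- list(
        chromosome = data.frame(id = chrom,
                                description = paste("synthetic", genome),
                                seq = asm$seq, stringsAsFactors = FALSE),
        genes = genes_to_df(ann$genes),
        gene_details = ann$genes,
        cds = ann$cds,
        layout = asm$layout
      )
      truth_borders[[genome]] <- data.frame(
        genome = genome, chrom = chrom, start = asm$locus_start,
        end = asm$locus_end, stringsAsFactors = FALSE)
      truth_genes[[genome]] <- data.frame(
        genome = genome,
        gene_index = vapply(ann$genes, `[[`, integer(1), "gene_index"),
        gene_id = vapply(ann$genes, `[[`, character(1), "gene_id"),
        chrom = chrom,
        start = vapply(ann$genes, `[[`, integer(1), "start"),
        end = vapply(ann$genes, `[[`, integer(1), "end"),
        strand = vapply(ann$genes, `[[`, character(1), "strand"),
        stringsAsFactors = FALSE)

      # marker truth positions from the segment layout
      lay <- asm$layout
      mk <- lapply(seq_len(cfg$n_markers), function(i) {
        seg_id <- anc[[marker_anchor$seg[i]]]$id
        k <- match(seg_id, lay$seg_id)
        if (is.na(k)) return(NULL)  # gene lost in this genome
        if (!lay$flipped[k]) {
          s <- lay$start[k] + marker_anchor$offset[i] - 1L
          e <- s + marker_anchor$len[i] - 1L
          strand <- "+"
        } else {
          e <- lay$end[k] - marker_anchor$offset[i] + 1L
          s <- e - marker_anchor$len[i] + 1L
          strand <- "-"
        }
        data.frame(genome = genome, marker_id = marker_anchor$marker_id[i],
                   chrom = chrom, start = s, end = e, strand = strand,
                   stringsAsFactors = FALSE)
      })
      truth_markers[[genome]] <- do.call(rbind, mk[!vapply(mk, is.null,
                                                           logical(1))])

      # hairpin truth positions
      hpk <- lapply(seq_along(hp_here), function(j) {
        k <- slots[j]
        seg_id <- segs[[k]]$id
        kk <- match(seg_id, lay$seg_id)
        hlen <- nchar(hp_here[[j]]$seq)
        s <- lay$start[kk] + hp_offset[j] - 1L
        data.frame(genome = genome, family = hp_here[[j]]$family,
                   mature_id = hp_here[[j]]$mature_id,
                   violate = hp_here[[j]]$violate, chrom = chrom,
                   start = s, end = s + hlen - 1L, strand = "+",
                   mat_from = s + hp_here[[j]]$mat_from - 1L,
                   mat_to = s + hp_here[[j]]$mat_to - 1L,
                   stringsAsFactors = FALSE)
      })
      truth_hairpins[[genome]] <- do.call(rbind, hpk)
    }

    structure(list(
      config = cfg,
      genomes = genomes_out,
      markers = markers,
      matures = matures,
      truth = list(
        borders = do.call(rbind, truth_borders),
        orthologs = do.call(rbind, truth_genes),
        markers = do.call(rbind, truth_markers),
        hairpins = do.call(rbind, truth_hairpins),
        target = target_truth,
        events = cfg$events
      )
    ), class = "locus_sim")
  })
}

#' @export
print.locus_sim <- function(x, ...) {
  cat("Synthetic locus set:", length(x$genomes), "genomes,",
      x$config$genes_per_locus, "ancestral genes,",
      nrow(x$markers), "markers,", nrow(x$matures), "planted matures\n")
  invisible(x)
}

#' Write a simulated locus set to a fixture directory
#'
#' Emits, per genome, `<genome>.fa` (chromosome), `<genome>.gff3` (gene
#' models) and `<genome>.cds.fa`, plus `markers.fa`, `matures.fa` and
#' `truth.json`.
#'
#' @param sim a `locus_sim`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "locus_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (genome in names(sim$genomes)) {
    g <- sim$genomes[[genome]]
    write_fasta(g$chromosome, file.path(dir, paste0(genome, ".fa")))
    write_fasta(g$cds, file.path(dir, paste0(genome, ".cds.fa")))
    write_gff3(g, file.path(dir, paste0(genome, ".gff3")))
  }
  write_fasta(sim$markers, file.path(dir, "markers.fa"))
  write_fasta(sim$matures, file.path(dir, "matures.fa"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# GFF3 writer for one simulated genome (gene/mRNA/CDS with ID/Parent links),
# via rtracklayer so the emitted dialect matches what read_gff_genes expects
write_gff3 <- function(g, path) {
  rows <- list()
  for (gene in g$gene_details) {
    rows[[length(rows) + 1]] <- data.frame(
      chrom = gene$chrom, start = gene$start, end = gene$end,
      strand = gene$strand, type = "gene", ID = gene$gene_id,
      Parent = NA_character_, stringsAsFactors = FALSE)
    for (iso in gene$isoforms) {
      tx_start <- min(vapply(iso$exons_chrom, `[`, integer(1), 1))
      tx_end <- max(vapply(iso$exons_chrom, `[`, integer(1), 2))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = gene$chrom, start = tx_start, end = tx_end,
        strand = gene$strand, type = "mRNA", ID = iso$transcript_id,
        Parent = gene$gene_id, stringsAsFactors = FALSE)
      for (e in iso$exons_chrom) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = gene$chrom, start = e[1], end = e[2],
          strand = gene$strand, type = "CDS", ID = NA_character_,
          Parent = iso$transcript_id, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID,
    Parent = IRanges::CharacterList(lapply(df$Parent, function(p)
      if (is.na(p)) character(0) else p)))
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}
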