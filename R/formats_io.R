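# Readers/writers for the external formats the pipeline touches.
#
# Conventions: all genomic coordinates in this package are 1-based inclusive
# (GFF/BLAST); BED export converts through to_bed_coords() in one place.
# Sequences are uppercased on read; U is mapped to T for DNA contexts and the
# miRNA module re-maps T -> U internally.

#' Read a FASTA file into a sequence-record data frame
#'
#' Records are returned in file order as a data frame with one row per record
#' and columns `id` (first whitespace-delimited token of the header),
#' `description` (remainder of the header) and `seq`. Sequences are uppercased;
#' for `alphabet = "dna"` any U is normalized to T. Duplicate ids and
#' characters outside the declared alphabet are errors.
#'
#' @param path path to a FASTA file
#' @param alphabet one of `"dna"`, `"rna"`, `"protein"`
#' @return data.frame with columns `id`, `description`, `seq`
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a test", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0 || all(!nzchar(trimws(readLines(path))))) {
    return(data.frame(id = character(), description = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) {
    return(data.frame(id = character(), description = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(id == "")) stop("empty sequence id in ", path)
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  seq <- toupper(as.character(set))
  if (alphabet == "dna") seq <- chartr("U", "T", seq)
  allowed <- switch(alphabet, dna = DNA_ALPHABET, rna = RNA_ALPHABET,
                    protein = AA_ALPHABET)
  bad <- !grepl(sprintf("^[%s]*$", paste(allowed, collapse = "")), seq)
  if (any(bad)) {
    stop("sequence(s) with characters outside the ", alphabet, " alphabet: ",
         paste(utils::head(id[bad], 5), collapse = ", "))
  }
  data.frame(id = unname(id), description = unname(description),
             seq = unname(seq), stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with columns `id`, `seq` and optionally
#'   `description`
#' @param path output path
#' @param width line width for wrapping
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  headers <- ifelse(is.na(desc) | desc == "", records$id,
                    paste(records$id, desc))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

HIT_COLS <- c("qid", "sid", "pident", "aln_len", "mismatches", "gap_opens",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore",
              "qlen", "slen")

#' Read a 14-column tabular alignment hit table
#'
#' Expects the 12 standard tabular columns plus query length and subject
#' length (the aligner's `"6 std qlen slen"` output). Minus-strand hits keep
#' `sstart > send` unmodified; normalization happens at interval-construction
#' time.
#'
#' @param path path to the tab-separated file (no header)
#' @return data.frame of alignment hits with columns `qid`, `sid`, `pident`,
#'   `aln_len`, `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, `qlen`, `slen`
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 14L)
  if (length(bad)) {
    stop("hit table row ", bad[1], " has ", nf[bad[1]],
         " columns; expected 14 (std + qlen + slen)")
  }
  m <- matrix(unlist(fields), ncol = 14L, byrow = TRUE)
  hits <- data.frame(
    qid = m[, 1], sid = m[, 2],
    pident = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    qlen = as.integer(m[, 13]), slen = as.integer(m[, 14]),
    stringsAsFactors = FALSE
  )
  validate_hits(hits)
  hits
}

#' Write an alignment hit table (14-column tabular)
#' @param hits hit data.frame as from [read_hit_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(HIT_COLS %in% names(hits)))
  utils::write.table(hits[, HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

empty_hits <- function() {
  data.frame(qid = character(), sid = character(), pident = numeric(),
             aln_len = integer(), mismatches = integer(),
             gap_opens = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), evalue = numeric(),
             bitscore = numeric(), qlen = integer(), slen = integer(),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  with(hits, {
    ok <- qstart >= 1 & qstart <= qend & qend <= qlen &
      pident >= 0 & pident <= 100 & aln_len >= 1
    if (any(!ok)) {
      stop("invalid alignment hit row(s): ",
           paste(utils::head(which(!ok), 5), collapse = ", "))
    }
  })
  invisible(hits)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features linked by ID/Parent. Per gene, each mRNA
#' isoform is recorded with its total CDS length (sum over CDS segment lengths,
#' `end - start + 1`). Genes without mRNA/CDS children (e.g. non-coding genes)
#' are kept with zero isoforms; downstream transcript extraction skips them.
#' CDS features whose parent cannot be resolved to a gene are skipped with a
#' warning.
#'
#' @param path path to a GFF3 file
#' @param chrom_filter optional character vector of chromosome names to keep
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and a list-column `isoforms` of data.frames
#'   (`transcript_id`, `cds_length`)
#' @export
read_gff_genes <- function(path, chrom_filter = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(chrom_filter)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% chrom_filter]
  }
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  cdss <- gr[type == "CDS"]

  mrna_parent <- vapply(mrnas$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  mrna_id <- as.character(mrnas$ID)

  cds_parent <- vapply(cdss$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  orphan <- !(cds_parent %in% mrna_id)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without resolvable parent mRNA ",
            "were skipped")
    cdss <- cdss[!orphan]
    cds_parent <- cds_parent[!orphan]
  }
  cds_len <- GenomicRanges::width(cdss)
  len_by_tx <- tapply(cds_len, cds_parent, sum)

  gene_ids <- as.character(genes$ID)
  iso_list <- lapply(gene_ids, function(g) {
    tx <- mrna_id[!is.na(mrna_parent) & mrna_parent == g]
    tx <- tx[tx %in% names(len_by_tx)]
    tx <- sort(tx)
    data.frame(transcript_id = tx,
               cds_length = as.integer(unname(len_by_tx[tx])),
               stringsAsFactors = FALSE)
  })
  out <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    stringsAsFactors = FALSE
  )
  out$isoforms <- iso_list
  out[order(out$chrom, out$start, out$end, out$gene_id), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Export locus intervals as BED6
#'
#' @param intervals interval data.frame as from [infer_interval()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_intervals_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  bed <- to_bed_coords(intervals$start, intervals$end)
  name <- if (!is.null(intervals$genome)) {
    paste(intervals$genome, intervals$method %||% "interval", sep = "|")
  } else rep("interval", nrow(intervals))
  df <- data.frame(intervals$chrom, bed$bed_start, bed$bed_end, name,
                   intervals$support %||% 0L, rep(".", nrow(intervals)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
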