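# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
RNA_ALPHABET <- c("A", "C", "G", "U", "N")
AA_ALPHABET <- c(LETTERS, "*", "-")  # permissive IUPAC amino acid incl. X etc.

#' Reverse complement of a DNA string
#' @param x character scalar (DNA, ACGTN)
#' @return character scalar
#' @keywords internal
#' @noRd
revcomp_dna <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' Reverse complement of an RNA string
#' @noRd
revcomp_rna <- function(x) {
  chartr("ACGUN", "UGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

dna_to_rna <- function(x) chartr("T", "U", x)
rna_to_dna <- function(x) chartr("U", "T", x)

#' Hamming distance between two equal-length strings
#' @noRd
hamming <- function(a, b) {
  ia <- utf8ToInt(a)
  ib <- utf8ToInt(b)
  stopifnot(length(ia) == length(ib))
  sum(ia != ib)
}

#' Convert a 1-based inclusive interval to BED (0-based half-open)
#'
#' The single place where the coordinate convention changes; everything else
#' in the package is 1-based inclusive (GFF/BLAST convention).
#'
#' @param start,end integer vectors, 1-based inclusive
#' @return data.frame with columns `bed_start`, `bed_end`
#' @export
to_bed_coords <- function(start, end) {
  stopifnot(all(start >= 1), all(start <= end))
  data.frame(bed_start = start - 1L, bed_end = end)
}

#' Run a block with a locally seeded RNG, restoring global state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
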