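#' Describe a circular genome
#'
#' Plant mitochondrial master genomes are conventionally reported as a single
#' circular molecule ("master circle") with 1-based inclusive coordinates.
#' `circular_genome()` builds the lightweight object the rest of the package
#' works with: a name, a length in bp, and optionally the nucleotide sequence.
#'
#' @param length Genome length in bp (positive integer).
#' @param name Molecule name.
#' @param sequence Optional nucleotide string of exactly `length` characters
#'   over `A`, `C`, `G`, `T`, `N` (case-insensitive; stored upper-case).
#' @return An object of class `circular_genome` with fields `name`, `length`
#'   and `sequence` (`NULL` when not supplied).
#' @examples
#' circular_genome(402558, name = "soybean_mt")
#' @export
circular_genome <- function(length, name = "genome", sequence = NULL) {
  length <- as.integer(length)
  stopifnot(base::length(length) == 1L, !is.na(length), length > 0L)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length) {
      stop("`sequence` has ", nchar(sequence), " characters but `length` is ",
           length, call. = FALSE)
    }
    if (grepl("[^ACGTN]", sequence)) {
      stop("`sequence` contains characters outside {A,C,G,T,N}", call. = FALSE)
    }
  }
  structure(list(name = name, length = length, sequence = sequence),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("<circular_genome> ", x$name, ": ", format(x$length, big.mark = ","),
      " bp", if (is.null(x$sequence)) " (no sequence)" else " (with sequence)",
      "\n", sep = "")
  invisible(x)
}

#' Read a circular genome from a FASTA file
#'
#' Reads the first record of a FASTA file as a circular molecule.
#'
#' @param path Path to a FASTA file.
#' @return A [circular_genome()].
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path, call. = FALSE)
  circular_genome(Biostrings::width(seqs)[1],
                  name = sub("\\s.*$", "", names(seqs)[1]),
                  sequence = as.character(seqs[[1]]))
}

#' Write a circular genome to a FASTA file
#'
#' @param genome A [circular_genome()] with sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "circular_genome"))
  if (is.null(genome$sequence)) stop("genome carries no sequence", call. = FALSE)
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Length of an interval on a circular genome
#'
#' Coordinates are 1-based and inclusive; an interval with `end < start`
#' wraps the origin. This is the only convention under which every printed
#' repeat-copy length in the soybean tables equals `end - start + 1`.
#'
#' @param start,end Interval coordinates in `[1, G]` (vectorised).
#' @param genome A [circular_genome()] or a genome length in bp.
#' @return Integer vector of interval lengths in bp.
#' @examples
#' copy_length(62957, 66865, 402558) # 3909
#' copy_length(991, 10, 1000)        # wraps the origin: 20
#' @export
copy_length <- function(start, end, genome) {
  G <- genome_length(genome)
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start) | is.na(end))) stop("NA coordinates", call. = FALSE)
  if (any(start < 1L | start > G | end < 1L | end > G)) {
    stop("coordinates outside [1, ", G, "]", call. = FALSE)
  }
  ifelse(end >= start, end - start + 1L, G - start + 1L + end)
}

genome_length <- function(genome) {
  if (inherits(genome, "circular_genome")) genome$length
  else {
    G <- as.integer(genome)
    stopifnot(length(G) == 1L, !is.na(G), G > 0L)
    G
  }
}

# 1-based position arithmetic on a circle of size n: map any integer to 1..n
circ_pos <- function(p, n) ((p - 1L) %% n) + 1L

# reverse-complement of a plain character string (base R; A/C/G/T/N)
revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x) {
    paste(rev(strsplit(x, NULL)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
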