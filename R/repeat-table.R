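#' Read a repeat annotation table
#'
#' Reads the tab-separated repeat-annotation dialect used throughout the
#' package: one row per repeat copy with columns `family`, `copy`, `begin`,
#' `end` and optionally `length`, `strand`, `identity` and `segments`
#' (comma-joined segment ids in family reference order; a trailing `*` marks
#' a non-homologous variant occupying the same slot, e.g. `S6*`). Numbers may
#' carry thousands separators, as published tables usually do.
#'
#' @param path Path to a TSV file.
#' @param genome_length Optional genome length in bp, needed to validate the
#'   `length` column for copies that wrap the origin.
#' @return A tibble of class `repeat_table` with columns `family`, `copy`,
#'   `start`, `end`, `length`, `strand`, `identity` and a list-column
#'   `segments`.
#' @examples
#' read_repeat_table(system.file("extdata", "soybean_mt_repeats.tsv",
#'                               package = "mtpool"))
#' @export
read_repeat_table <- function(path, genome_length = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  as_repeat_table(raw, genome_length = genome_length)
}

#' Coerce a data frame to a validated repeat table
#'
#' @param x A data frame with at least `family`, `copy` (or `name`),
#'   `begin`/`start` and `end` columns.
#' @inheritParams read_repeat_table
#' @return A `repeat_table` tibble; see [read_repeat_table()].
#' @export
as_repeat_table <- function(x, genome_length = NULL) {
  x <- tibble::as_tibble(x)
  names(x) <- tolower(names(x))
  if ("name" %in% names(x) && !"copy" %in% names(x)) {
    names(x)[names(x) == "name"] <- "copy"
  }
  if ("begin" %in% names(x) && !"start" %in% names(x)) {
    names(x)[names(x) == "begin"] <- "start"
  }
  need <- c("family", "copy", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("repeat table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- function(v) {
    if (is.character(v)) v <- gsub("[, ]", "", v)
    suppressWarnings(as.numeric(v))
  }
  out <- tibble::tibble(
    family = as.character(x$family),
    copy = as.character(x$copy),
    start = as.integer(num(x$start)),
    end = as.integer(num(x$end))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    stop("unparseable coordinates in repeat table", call. = FALSE)
  }
  # strand: required per row; "forward"/"reverse" (also +/-)
  if ("strand" %in% names(x) || "orientation" %in% names(x)) {
    s <- if ("strand" %in% names(x)) x$strand else x$orientation
    s <- tolower(trimws(as.character(s)))
    s[s %in% c("+", "f", "fwd")] <- "forward"
    s[s %in% c("-", "r", "rev")] <- "reverse"
    bad <- !(s %in% c("forward", "reverse"))
    if (any(bad)) {
      stop("unknown strand for copy ", paste(out$copy[bad], collapse = ", "),
           call. = FALSE)
    }
    out$strand <- s
  } else {
    stop("repeat table has no strand/orientation column and no default applies",
         call. = FALSE)
  }
  implied <- if (is.null(genome_length)) {
    ifelse(out$end >= out$start, out$end - out$start + 1L, NA_integer_)
  } else {
    copy_length(out$start, out$end, genome_length)
  }
  if ("length" %in% names(x)) {
    len <- as.integer(num(x$length))
    bad <- !is.na(len) & !is.na(implied) & len != implied
    if (any(bad)) {
      stop("length column disagrees with coordinates for copy ",
           paste(out$copy[bad], collapse = ", "),
           " (printed ", paste(len[bad], collapse = ", "),
           ", end - start + 1 gives ", paste(implied[bad], collapse = ", "), ")",
           call. = FALSE)
    }
    out$length <- ifelse(is.na(len), implied, len)
  } else {
    out$length <- implied
  }
  out$identity <- if ("identity" %in% names(x)) {
    v <- as.character(x$identity)
    v <- gsub("%", "", v)
    v <- suppressWarnings(as.numeric(v))
    ifelse(!is.na(v) & v > 1, v / 100, v)
  } else NA_real_
  out$segments <- if ("segments" %in% names(x) && is.list(x$segments)) {
    lapply(x$segments, as.character)
  } else if ("segments" %in% names(x)) {
    lapply(as.character(x$segments), function(s) {
      if (is.na(s) || s %in% c("", ".", "-")) character(0)
      else trimws(strsplit(s, ",")[[1]])
    })
  } else {
    rep(list(character(0)), nrow(out))
  }
  dup <- duplicated(out$copy)
  if (any(dup)) stop("duplicated copy ids: ",
                     paste(unique(out$copy[dup]), collapse = ", "), call. = FALSE)
  class(out) <- c("repeat_table", class(out))
  out
}

#' Write a repeat table
#'
#' Inverse of [read_repeat_table()]; segments are comma-joined.
#'
#' @param x A `repeat_table` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(x, path) {
  out <- tibble::tibble(
    family = x$family, copy = x$copy, begin = x$start, end = x$end,
    length = x$length, strand = x$strand, identity = x$identity,
    segments = vapply(x$segments, function(s) {
      if (length(s) == 0) "." else paste(s, collapse = ",")
    }, character(1))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a segment-length catalog
#'
#' A catalog gives the length of every named segment per family, keyed by
#' `(family, segment)`. Variant segments carry a `*` suffix and occupy the
#' slot of the base segment they replace.
#'
#' @param path Path to a TSV with columns `family`, `segment`, `length`.
#' @return A tibble with columns `family`, `segment`, `length` (and any
#'   extra columns preserved).
#' @export
read_segment_catalog <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(out) <- tolower(names(out))
  stopifnot(all(c("family", "segment", "length") %in% names(out)))
  out$length <- as.integer(gsub("[, ]", "", out$length))
  tibble::as_tibble(out)
}

#' Published repeat annotation of the soybean mitochondrial genome
#'
#' The large-repeat annotation of the 402,558-bp soybean (*Glycine max*)
#' mitochondrial master circle: four homology families totalling 59,273 bp
#' across 11 copies. Family R1 has five nested copies whose shared-segment
#' compositions (S1--S7, with the non-homologous variant S6*) drive the
#' genome's recombinational complexity.
#'
#' `soybean_mt_repeats()` returns the copy table, `soybean_mt_segments()`
#' the segment-length catalog (see the package vignette for how the
#' underdetermined segment lengths are pinned from the published extremes),
#' `soybean_mt_features()` the genome-composition feature totals, and
#' `soybean_mt_genome()` the master circle (length only; the sequence itself
#' is not shipped).
#'
#' @return A tibble (or [circular_genome()] for `soybean_mt_genome()`).
#' @examples
#' soybean_mt_repeats()
#' @export
soybean_mt_repeats <- function() {
  read_repeat_table(
    system.file("extdata", "soybean_mt_repeats.tsv", package = "mtpool"),
    genome_length = 402558L
  )
}

#' @rdname soybean_mt_repeats
#' @export
soybean_mt_segments <- function() {
  read_segment_catalog(
    system.file("extdata", "soybean_mt_segments.tsv", package = "mtpool")
  )
}

#' @rdname soybean_mt_repeats
#' @export
soybean_mt_features <- function() {
  readr::read_tsv(
    system.file("extdata", "soybean_mt_features.tsv", package = "mtpool"),
    col_types = "ci", progress = FALSE
  )
}

#' @rdname soybean_mt_repeats
#' @export
soybean_mt_genome <- function() {
  circular_genome(402558L, name = "soybean_mt")
}
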