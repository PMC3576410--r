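# ---- synthetic circular genomes with planted repeat structure ---------

#' Build a simulation configuration
#'
#' Describes a circular genome with planted multi-copy repeat families
#' (copies are contiguous slot-runs of a progenitor segment sequence, in
#' either orientation, optionally with non-homologous variant slots --- the
#' S6/S6* device), uniformly placed short dispersed repeats, tandem arrays
#' and annotation tracks. Defaults emulate the published organelle regime:
#' 45% GC background and near-identical repeat copies.
#'
#' @param genome_length Genome length in bp.
#' @param families List of family specs; each a list with `family`,
#'   `segment_lengths` (named bp vector in reference order; names with a
#'   `*` suffix define variant content for the base slot), and `copies`, a
#'   list of `list(copy, from, to, strand, start = NULL, variants =
#'   character(0))` where `from`/`to` name the slot range and `variants`
#'   names variant content ids carried by this copy.
#' @param divergence Per-copy substitution rate in `[0, 0.2]` applied to
#'   every non-reference copy.
#' @param gc Background GC fraction (default 0.45).
#' @param short_repeats `list(count, length)`: copies of one short source
#'   sequence placed uniformly, or `NULL`.
#' @param tandem List of `list(unit, copies)` tandem arrays, or `NULL`.
#' @param tracks Named integer vector: target bp per annotation category,
#'   or `NULL`.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(genome_length, families = list(), divergence = 0,
                       gc = 0.45, short_repeats = NULL, tandem = NULL,
                       tracks = NULL) {
  stopifnot(genome_length > 0, divergence >= 0, divergence <= 0.2,
            gc > 0, gc < 1)
  for (f in families) {
    stopifnot(!is.null(f$family), !is.null(f$segment_lengths),
              !is.null(names(f$segment_lengths)), length(f$copies) >= 1)
  }
  structure(list(genome_length = as.integer(genome_length),
                 families = families, divergence = divergence, gc = gc,
                 short_repeats = short_repeats, tandem = tandem,
                 tracks = tracks),
            class = "sim_config")
}

rand_seq <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, NULL)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

#' Simulate a circular genome with planted repeats
#'
#' Deterministic given `seed`: emits the genome (with sequence) and a truth
#' table describing everything planted, in the same dialect the analysis
#' functions consume, so detection and recombination results can be checked
#' against ground truth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A list with elements `genome` (a [circular_genome()]),
#'   `repeats` (planted `repeat_table`), `catalog` (segment catalog),
#'   `short` (tibble of planted short-repeat intervals), `tandem`,
#'   `tracks`, and `expected` (analytic pair and single-event product
#'   counts; see [expected_pool()]).
#' @export
simulate_genome <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  G <- config$genome_length
  base <- strsplit(rand_seq(G, config$gc), NULL)[[1]]

  occupied <- logical(G) # rejection sampling forbids overlapping plants
  claim <- function(start, len) {
    if (start < 1 || start + len - 1L > G) return(FALSE)
    idx <- seq.int(start, start + len - 1L)
    if (any(occupied[idx])) return(FALSE)
    occupied[idx] <<- TRUE
    TRUE
  }
  place <- function(len, start = NULL) {
    if (!is.null(start)) {
      if (!claim(start, len)) stop("planted features overlap at ", start,
                                   call. = FALSE)
      return(as.integer(start))
    }
    for (try in 1:2000) {
      s <- sample.int(G - len, 1)
      if (claim(s, len)) return(s)
    }
    stop("infeasible packing: cannot place a ", len, " bp feature",
         call. = FALSE)
  }

  rep_rows <- list(); cat_rows <- list()
  for (f in config$families) {
    seg_names <- names(f$segment_lengths)
    base_slots <- seg_names[!grepl("\\*$", seg_names)]
    seg_seq <- lapply(f$segment_lengths, function(n) rand_seq(n, config$gc))
    names(seg_seq) <- seg_names
    for (ci in seq_along(f$copies)) {
      cp <- f$copies[[ci]]
      i1 <- match(cp$from, base_slots); i2 <- match(cp$to, base_slots)
      stopifnot(!is.na(i1), !is.na(i2), i1 <= i2)
      slots <- base_slots[i1:i2]
      content <- slots
      for (v in cp$variants %||% character(0)) {
        content[match(sub("\\*$", "", v), slots)] <- v
      }
      s <- paste(unlist(seg_seq[content]), collapse = "")
      if (ci > 1) s <- mutate_seq(s, config$divergence)
      strand <- cp$strand %||% "forward"
      if (strand == "reverse") s <- revcomp_chr(s)
      len <- nchar(s)
      start <- place(len, cp$start)
      base[seq.int(start, start + len - 1L)] <- strsplit(s, NULL)[[1]]
      rep_rows[[length(rep_rows) + 1L]] <- tibble::tibble(
        family = f$family, copy = cp$copy, start = start,
        end = start + len - 1L, length = len, strand = strand,
        identity = if (ci > 1) 1 - config$divergence else 1,
        segments = list(content)
      )
    }
    cat_rows[[length(cat_rows) + 1L]] <- tibble::tibble(
      family = f$family, segment = seg_names,
      length = as.integer(f$segment_lengths)
    )
  }

  short_tbl <- tibble::tibble(start = integer(), end = integer())
  if (!is.null(config$short_repeats)) {
    sr <- config$short_repeats
    src <- rand_seq(sr$length, config$gc)
    starts <- vapply(seq_len(sr$count), function(i) place(sr$length), integer(1))
    for (s in starts) {
      base[seq.int(s, s + sr$length - 1L)] <- strsplit(src, NULL)[[1]]
    }
    short_tbl <- tibble::tibble(start = sort(starts),
                                end = sort(starts) + sr$length - 1L)
  }

  tandem_tbl <- tibble::tibble(start = integer(), unit_length = integer(),
                               copy_count = numeric())
  if (!is.null(config$tandem)) {
    rows <- list()
    for (td in config$tandem) {
      unit <- rand_seq(td$unit, config$gc)
      arr <- strrep(unit, td$copies)
      s <- place(nchar(arr), td$start %||% NULL)
      base[seq.int(s, s + nchar(arr) - 1L)] <- strsplit(arr, NULL)[[1]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = s, unit_length = td$unit, copy_count = td$copies)
    }
    tandem_tbl <- purrr::list_rbind(rows)
  }

  tracks_tbl <- NULL
  if (!is.null(config$tracks)) {
    pos <- 1L; rows <- list()
    for (i in seq_along(config$tracks)) {
      bp <- as.integer(config$tracks[[i]])
      rows[[i]] <- tibble::tibble(category = names(config$tracks)[i],
                                  start = pos, end = pos + bp - 1L)
      pos <- pos + bp
    }
    tracks_tbl <- purrr::list_rbind(rows)
    if (pos - 1L > G) stop("tracks exceed genome length", call. = FALSE)
  }

  repeats <- if (length(rep_rows) > 0) {
    as_repeat_table(purrr::list_rbind(rep_rows), genome_length = G)
  } else {
    as_repeat_table(tibble::tibble(family = character(), copy = character(),
                                   start = integer(), end = integer(),
                                   strand = character()), genome_length = G)
  }
  catalog <- if (length(cat_rows) > 0) purrr::list_rbind(cat_rows) else
    tibble::tibble(family = character(), segment = character(),
                   length = integer())

  list(
    genome = circular_genome(G, name = "synthetic_circle",
                             sequence = paste(base, collapse = "")),
    repeats = repeats, catalog = catalog, short = short_tbl,
    tandem = tandem_tbl, tracks = tracks_tbl,
    expected = expected_pool(config),
    config = config, seed = seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic expectations for a simulated repeat system
#'
#' Counts repeat pairs and single-event recombination products directly
#' from the configuration, independently of the detection and recombination
#' machinery: two copies pair when their slot runs overlap with matching
#' content (variant slots are non-homologous) over at least `min_shared`
#' bp; each direct pair contributes two subgenomic circles, each inverted
#' pair one isometric isomer.
#'
#' @param config A [sim_config()].
#' @param min_shared Minimum shared bp for a pair (default 500).
#' @return A one-row tibble: `n_pairs`, `n_direct`, `n_inverted`,
#'   `n_subcircles`, `n_isomers`.
#' @export
expected_pool <- function(config, min_shared = 500) {
  n_direct <- 0L; n_inverted <- 0L
  for (f in config$families) {
    seg_names <- names(f$segment_lengths)
    base_slots <- seg_names[!grepl("\\*$", seg_names)]
    info <- lapply(f$copies, function(cp) {
      i1 <- match(cp$from, base_slots); i2 <- match(cp$to, base_slots)
      content <- base_slots[i1:i2]
      for (v in cp$variants %||% character(0)) {
        content[match(sub("\\*$", "", v), content)] <- v
      }
      list(lo = i1, hi = i2, content = content,
           strand = cp$strand %||% "forward")
    })
    nc <- length(info)
    if (nc < 2) next
    for (i in seq_len(nc - 1L)) {
      for (j in seq(i + 1L, nc)) {
        a <- info[[i]]; b <- info[[j]]
        lo <- max(a$lo, b$lo); hi <- min(a$hi, b$hi)
        if (lo > hi) next
        ks <- seq(lo, hi)
        ca <- a$content[ks - a$lo + 1]; cb <- b$content[ks - b$lo + 1]
        shared <- ca[ca == cb]
        if (length(shared) == 0) next
        if (sum(f$segment_lengths[shared]) < min_shared) next
        if (a$strand == b$strand) n_direct <- n_direct + 1L
        else n_inverted <- n_inverted + 1L
      }
    }
  }
  tibble::tibble(
    n_pairs = n_direct + n_inverted,
    n_direct = n_direct, n_inverted = n_inverted,
    n_subcircles = 2L * n_direct, n_isomers = n_inverted
  )
}

#' A simulation configuration mirroring the soybean repeat topology
#'
#' One five-copy nested family with seven segments plus a variant slot, one
#' direct two-copy family and two inverted two-copy families on a 100-kb
#' circle: the repeat system that yields 13 pairs (5 direct, 8 inverted),
#' 10 single-event subgenomic circles and 8 isomers.
#'
#' @param genome_length Circle size in bp (default 100000).
#' @param divergence Per-copy substitution rate (default 0).
#' @return A [sim_config()].
#' @export
soybean_like_config <- function(genome_length = 100000, divergence = 0) {
  segs <- c(S1 = 983L, S2 = 1922L, S3 = 156L, S4 = 1041L, S5 = 776L,
            S6 = 518L, S7 = 518L, `S6*` = 673L)
  fam_r1 <- list(
    family = "R1", segment_lengths = segs,
    copies = list(
      list(copy = "R1e", from = "S1", to = "S7", strand = "forward"),
      list(copy = "R1a", from = "S3", to = "S7", strand = "reverse"),
      list(copy = "R1b", from = "S2", to = "S6", strand = "forward",
           variants = "S6*"),
      list(copy = "R1c", from = "S4", to = "S6", strand = "reverse",
           variants = "S6*"),
      list(copy = "R1d", from = "S1", to = "S4", strand = "forward")
    )
  )
  two_copy <- function(fam, len, strand2) {
    list(family = fam, segment_lengths = stats::setNames(as.integer(len), "S1"),
         copies = list(
           list(copy = paste0(fam, "a"), from = "S1", to = "S1",
                strand = "forward"),
           list(copy = paste0(fam, "b"), from = "S1", to = "S1",
                strand = strand2)
         ))
  }
  sim_config(
    genome_length = genome_length,
    families = list(fam_r1,
                    two_copy("R2", 1692, "forward"),
                    two_copy("R3", 2161, "reverse"),
                    two_copy("R4", 1692, "reverse")),
    divergence = divergence
  )
}
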