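# ---- genome composition ledger ----------------------------------------

ledger_categories <- c(
  "protein_exon", "cis_intron", "rRNA", "tRNA",
  "chloroplast_like", "nuclear_like", "mitochondrial_like",
  "bacterial_mitovirus_like", "nuclear_shared", "unknown"
)

#' Genome-composition ledger over annotation tracks
#'
#' Accounts every position of a circular genome to one category. Tracks are
#' interval annotations (1-based inclusive); positions claimed by more than
#' one category are resolved by the priority order (first listed wins), and
#' positions claimed by none fall to `unknown`. Percentages are bp divided
#' by genome length times 100; conservation (categories plus residual sum
#' to the genome length) holds by construction.
#'
#' @param genome A [circular_genome()] or genome length in bp.
#' @param tracks A data frame with columns `category`, `start`, `end`
#'   (1-based inclusive master coordinates), or a named list of such data
#'   frames / BED / GFF3 file paths (names give the categories). BED input
#'   (0-based half-open) is converted on read.
#' @param priority Category resolution order; defaults to coding categories
#'   (exon > intron > rRNA > tRNA) before provenance categories.
#' @param residual Category receiving positions claimed by no track
#'   (default `"unknown"`).
#' @return A tibble of class `composition_ledger` with columns `category`,
#'   `bp`, `percent` (full precision) and `percent_printed` (2 decimals).
#' @examples
#' build_ledger(402558, tibble::tibble(category = "protein_exon",
#'                                     start = 1, end = 34133))
#' @export
build_ledger <- function(genome, tracks, priority = ledger_categories,
                         residual = "unknown") {
  G <- genome_length(genome)
  tracks <- standardise_tracks(tracks)
  bad <- tracks$start < 1 | tracks$end > G | tracks$end < tracks$start
  if (any(bad)) {
    stop("interval out of range [1, ", G, "] in track(s): ",
         paste(unique(tracks$category[bad]), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(unique(tracks$category), c(priority, residual))
  priority <- c(setdiff(priority, residual), extra, residual)
  owner <- integer(G) # 0 = unclaimed
  for (i in seq_along(priority)) {
    sub <- tracks[tracks$category == priority[i], ]
    if (nrow(sub) == 0) next
    for (j in seq_len(nrow(sub))) {
      idx <- seq.int(sub$start[j], sub$end[j])
      idx <- idx[owner[idx] == 0L]
      owner[idx] <- i
    }
  }
  owner[owner == 0L] <- match(residual, priority)
  bp <- tabulate(owner, nbins = length(priority))
  out <- tibble::tibble(
    category = priority,
    bp = bp,
    percent = bp / G * 100,
    percent_printed = round(bp / G * 100, 2)
  )
  out <- out[out$bp > 0 | out$category %in% unique(tracks$category) |
               out$category == residual, ]
  attr(out, "genome_length") <- G
  class(out) <- c("composition_ledger", class(out))
  out
}

standardise_tracks <- function(tracks) {
  if (is.data.frame(tracks)) {
    stopifnot(all(c("category", "start", "end") %in% names(tracks)))
    return(tibble::tibble(category = as.character(tracks$category),
                          start = as.integer(tracks$start),
                          end = as.integer(tracks$end)))
  }
  if (is.list(tracks)) {
    stopifnot(!is.null(names(tracks)))
    purrr::imap(tracks, function(tr, nm) {
      if (is.character(tr)) tr <- read_track_file(tr)
      tibble::tibble(category = nm, start = as.integer(tr$start),
                     end = as.integer(tr$end))
    }) |> purrr::list_rbind()
  } else {
    stop("`tracks` must be a data frame or a named list", call. = FALSE)
  }
}

# BED (0-based half-open) or GFF3 (1-based inclusive) via rtracklayer
read_track_file <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading track files requires the rtracklayer package", call. = FALSE)
  }
  df <- as.data.frame(rtracklayer::import(path))
  tibble::tibble(start = df$start, end = df$end)
}

#' Plot a composition ledger
#'
#' @param object A `composition_ledger`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composition_ledger <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$category <- factor(df$category, levels = rev(df$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent, y = .data$category)) +
    ggplot2::geom_col(fill = "darkolivegreen4") +
    ggplot2::labs(x = "% of genome", y = NULL,
                  title = "Genome composition") +
    ggplot2::theme_minimal()
}

# ---- uniformity of genomic positions ----------------------------------

#' Test uniformity of positions on a circular genome
#'
#' Tests whether genomic positions (e.g. repeat midpoints) are uniformly
#' distributed. In circular mode (default) the rotation-invariant Kuiper
#' statistic \eqn{V = D^+ + D^-} is used, the appropriate analogue of the
#' Kolmogorov--Smirnov statistic on a circle, with the standard asymptotic
#' tail series for the p-value. In linear mode the one-sample
#' Kolmogorov--Smirnov test against the uniform CDF is used (via
#' [stats::ks.test()]).
#'
#' @param positions Numeric vector of positions in bp (at least 5).
#' @param genome A [circular_genome()] or genome length in bp.
#' @param circular Use the rotation-invariant Kuiper form (default `TRUE`).
#' @return A tibble with `statistic`, `p_value`, `n` and `method`.
#' @examples
#' ks_uniformity(c(10, 210, 400, 610, 790), 1000)
#' @export
ks_uniformity <- function(positions, genome, circular = TRUE) {
  G <- genome_length(genome)
  positions <- as.numeric(positions)
  n <- length(positions)
  if (n < 5) stop("need at least 5 positions (test underpowered)", call. = FALSE)
  if (any(positions < 0 | positions > G)) {
    stop("positions outside [0, ", G, "]", call. = FALSE)
  }
  u <- sort((positions %% G) / G)
  i <- seq_len(n)
  d_plus <- max(i / n - u)
  d_minus <- max(u - (i - 1) / n)
  if (circular) {
    v <- d_plus + d_minus
    lambda <- v * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
    j <- 1:100
    p <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(max(p, 0), 1)
    tibble::tibble(statistic = v, p_value = p, n = n, method = "Kuiper (circular)")
  } else {
    kt <- suppressWarnings(stats::ks.test(u, "punif"))
    tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
                   n = n, method = "Kolmogorov-Smirnov (linear)")
  }
}
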