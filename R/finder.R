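# ---- repeat discovery by genome self-comparison -----------------------
#
# Seed-and-extend self-comparison tuned for the organelle regime: repeats of
# interest are >= 99% identical over hundreds to thousands of bp, diverged
# by substitutions. Exact 21-mer seeds are chained along diagonals
# (forward) or anti-diagonals (reverse) and extended ungapped. The circle
# is handled by scanning a doubled linearization, so origin-spanning
# repeats are found, and mapping hits back to circular coordinates.

kmer_index <- function(s, k) {
  n <- nchar(s) - k + 1L
  kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
  split(seq_len(n), kmers)
}

# chain seed positions sharing a diagonal into runs with gaps <= max_gap
chain_runs <- function(pos, k, max_gap) {
  pos <- sort(pos)
  brk <- c(0L, which(diff(pos) > max_gap), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i) {
    p <- pos[(brk[i] + 1L):brk[i + 1L]]
    c(p[1], p[length(p)] + k - 1L)
  })
}

# ungapped identity between two equal-length stretches of a raw vector
raw_identity <- function(x, a, b, len) {
  if (len <= 0) return(0)
  mean(x[a:(a + len - 1L)] == x[b:(b + len - 1L)])
}

# extend [a1,a2] in x against [b1,...] in y outward while bases match
extend_exact2 <- function(x, y, a1, a2, b1) {
  len <- a2 - a1 + 1L
  b2 <- b1 + len - 1L
  while (a1 > 1L && b1 > 1L && x[a1 - 1L] == y[b1 - 1L]) {
    a1 <- a1 - 1L; b1 <- b1 - 1L
  }
  nx <- length(x); ny <- length(y)
  while (a2 < nx && b2 < ny && x[a2 + 1L] == y[b2 + 1L]) {
    a2 <- a2 + 1L; b2 <- b2 + 1L
  }
  c(a1, a2, b1, b2)
}

self_hits <- function(genome, k = 21, max_gap = 200, min_len = 50,
                      min_identity = 0.9, max_group = 100) {
  if (is.null(genome$sequence)) {
    stop("genome has no sequence; use the table-driven interface instead",
         call. = FALSE)
  }
  G <- genome$length
  seq1 <- genome$sequence
  dbl <- paste0(seq1, seq1)
  x <- charToRaw(dbl)
  # index the single circle; extension runs on the doubled string so hits
  # may extend past the origin
  idx <- kmer_index(seq1, k)
  idx <- idx[lengths(idx) >= 2 & lengths(idx) <= max_group]

  # forward: diagonals d = p2 - p1
  pair_mat <- do.call(rbind, lapply(idx, function(p) {
    m <- length(p)
    i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
    j <- sequence((m - 1L):1L) + i
    cbind(p[i], p[j])
  }))
  fwd <- list()
  diag_seeds <- list()
  if (!is.null(pair_mat) && nrow(pair_mat) > 0) {
    d <- pair_mat[, 2] - pair_mat[, 1]
    keep_d <- d %% G != 0L
    diag_seeds <- split(pair_mat[keep_d, 1], d[keep_d])
  }
  for (key in names(diag_seeds)) {
    d <- as.integer(key)
    for (run in chain_runs(unique(diag_seeds[[key]]), k, max_gap)) {
      ext <- extend_exact2(x, x, run[1], run[2], run[1] + d)
      len <- ext[2] - ext[1] + 1L
      len <- min(len, abs(d), G) # avoid self-overlap along the diagonal
      ext[2] <- ext[1] + len - 1L
      if (len < min_len) next
      idy <- raw_identity(x, ext[1], ext[1] + d, len)
      if (idy < min_identity) next
      fwd[[length(fwd) + 1L]] <- c(ext[1], ext[2], ext[1] + d, ext[2] + d,
                                   1L, round(idy * 1e6))
    }
  }

  # reverse: match k-mers of the doubled sequence against its reverse
  # complement; anti-diagonal c = p1 + p2 is constant along a hit
  rc <- revcomp_chr(dbl)
  # all k-mers of the single circle against the reverse complement of the
  # doubled string (so the partner interval may wrap the origin)
  all_idx <- kmer_index(seq1, k)
  rc_idx <- kmer_index(rc, k)
  common <- intersect(names(all_idx), names(rc_idx))
  n_dbl <- 2L * G
  anti_mat <- do.call(rbind, lapply(common, function(km) {
    ps <- all_idx[[km]]; qs <- rc_idx[[km]]
    if (length(ps) * length(qs) > max_group^2) return(NULL)
    cbind(rep(ps, each = length(qs)), rep(qs, times = length(ps)))
  }))
  anti_seeds <- list()
  if (!is.null(anti_mat) && nrow(anti_mat) > 0) {
    p2 <- n_dbl - anti_mat[, 2] - k + 2L
    keep_a <- p2 != anti_mat[, 1]
    anti_seeds <- split(anti_mat[keep_a, 1], anti_mat[keep_a, 1] + p2[keep_a])
  }
  xr <- charToRaw(rc)
  rev_hits <- list()
  for (key in names(anti_seeds)) {
    cc <- as.integer(key)
    # along the hit, rc position q = p + delta
    delta <- n_dbl - cc - k + 2L
    for (run in chain_runs(unique(anti_seeds[[key]]), k, max_gap)) {
      ext <- extend_exact2(x, xr, run[1], run[2], run[1] + delta)
      a1 <- ext[1]; a2 <- ext[2]; q1 <- ext[3]; q2 <- ext[4]
      len <- a2 - a1 + 1L
      if (len < min_len || len > G) next
      idy <- mean(x[a1:a2] == xr[q1:q2])
      if (idy < min_identity) next
      b1f <- n_dbl - q2 + 1L # partner interval on the forward strand
      b2f <- n_dbl - q1 + 1L
      if (b1f == a1) next
      rev_hits[[length(rev_hits) + 1L]] <- c(a1, a2, b1f, b2f, -1L,
                                             round(idy * 1e6))
    }
  }

  hits <- c(fwd, rev_hits)
  if (length(hits) == 0) {
    return(tibble::tibble(start_a = integer(), end_a = integer(),
                          start_b = integer(), end_b = integer(),
                          strand_relation = character(), identity = numeric(),
                          length = integer()))
  }
  m <- do.call(rbind, hits)
  # map to circular coordinates and deduplicate copies of the same hit
  circ <- function(p) ((p - 1L) %% G) + 1L
  keys <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    ia <- sort(c(circ(m[i, 1]), circ(m[i, 2])))
    ib <- sort(c(circ(m[i, 3]), circ(m[i, 4])))
    both <- if (paste(ia, collapse = ",") <= paste(ib, collapse = ",")) {
      c(ia, ib)
    } else c(ib, ia)
    keys[i] <- paste(c(both, m[i, 5]), collapse = ":")
  }
  keep <- !duplicated(keys)
  # drop hits whose two circular intervals coincide (self-matches)
  same <- circ(m[, 1]) == circ(m[, 3]) & circ(m[, 2]) == circ(m[, 4])
  m <- m[keep & !same, , drop = FALSE]
  tibble::tibble(
    start_a = circ(m[, 1]), end_a = circ(m[, 2]),
    start_b = circ(m[, 3]), end_b = circ(m[, 4]),
    strand_relation = ifelse(m[, 5] == 1L, "forward", "reverse"),
    identity = m[, 6] / 1e6,
    length = copy_length(circ(m[, 1]), circ(m[, 2]), G)
  )
}

#' Find large repeats and group them into homology families
#'
#' Genome self-comparison by exact-seed chaining and ungapped extension on
#' both strands; hits of at least `min_len` bp and `min_identity` are
#' clustered into repeat copies, and copies are grouped into families by
#' single-linkage over pairwise hits (partial homology, as in nested repeat
#' systems, links copies that never align full-length).
#'
#' @param genome A [circular_genome()] with sequence.
#' @param min_len Minimum repeat length in bp (default 1000, the
#'   conventional large-repeat floor).
#' @param min_identity Minimum ungapped identity (default 0.90).
#' @param k Seed length (default 21).
#' @param max_gap Maximum gap between chained seeds (default 200).
#' @return A `repeat_table` tibble (one row per copy, families `F1`,
#'   `F2`, ...), with the underlying hit table as attribute `hits`.
#' @export
find_large_repeats <- function(genome, min_len = 1000, min_identity = 0.90,
                               k = 21, max_gap = 200) {
  hits <- self_hits(genome, k = k, max_gap = max_gap, min_len = min_len,
                    min_identity = min_identity)
  hits <- hits[hits$length >= min_len, ]
  G <- genome$length
  if (nrow(hits) == 0) {
    out <- as_repeat_table(tibble::tibble(
      family = character(), copy = character(), start = integer(),
      end = integer(), strand = character()), genome_length = G)
    attr(out, "hits") <- hits
    return(out)
  }
  # collect copy intervals from both hit sides, cluster by reciprocal overlap
  iv <- rbind(cbind(hits$start_a, hits$end_a), cbind(hits$start_b, hits$end_b))
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  ov_len <- function(i, j) {
    # overlap of two circular intervals, approximated on the linearization
    s1 <- iv[i, 1]; e1 <- iv[i, 1] + copy_length(iv[i, 1], iv[i, 2], G) - 1L
    s2 <- iv[j, 1]; e2 <- iv[j, 1] + copy_length(iv[j, 1], iv[j, 2], G) - 1L
    max(0L, min(e1, e2) - max(s1, s2) + 1L)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      li <- copy_length(iv[i, 1], iv[i, 2], G)
      lj <- copy_length(iv[j, 1], iv[j, 2], G)
      if (ov_len(i, j) >= 0.5 * min(li, lj)) union_(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  copy_id <- match(comp, unique(comp))
  # one interval per copy: the union of its cluster's hit intervals
  # (computed on the linearization, mapped back to the circle)
  copies <- purrr::map(unique(copy_id), function(cid) {
    sel <- which(copy_id == cid)
    s <- iv[sel, 1]
    e <- iv[sel, 1] + copy_length(iv[sel, 1], iv[sel, 2], G) - 1L
    c(min(s), circ_pos(max(e), G))
  })
  # family = connected components of copies linked by hits
  nc <- length(copies)
  fparent <- seq_len(nc)
  ffind <- function(i) { while (fparent[i] != i) i <- fparent[i]; i }
  funion <- function(i, j) {
    ri <- ffind(i); rj <- ffind(j)
    if (ri != rj) fparent[rj] <<- ri
  }
  hit_copy_a <- copy_id[seq_len(nrow(hits))]
  hit_copy_b <- copy_id[nrow(hits) + seq_len(nrow(hits))]
  for (h in seq_len(nrow(hits))) funion(hit_copy_a[h], hit_copy_b[h])
  fam_of <- vapply(seq_len(nc), ffind, integer(1))
  fam_id <- match(fam_of, unique(fam_of))
  # strand assignment: BFS over hit graph, forward/reverse by hit relation
  strand <- rep(NA_integer_, nc)
  for (root in seq_len(nc)) {
    if (!is.na(strand[root])) next
    strand[root] <- 1L
    queue <- root
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (h in seq_len(nrow(hits))) {
        pair <- c(hit_copy_a[h], hit_copy_b[h])
        if (!cur %in% pair) next
        other <- pair[pair != cur][1]
        rel <- if (hits$strand_relation[h] == "forward") 1L else -1L
        if (is.na(strand[other])) {
          strand[other] <- strand[cur] * rel
          queue <- c(queue, other)
        }
      }
    }
  }
  mean_idy <- vapply(seq_len(nc), function(cid) {
    sel <- hit_copy_a == cid | hit_copy_b == cid
    mean(hits$identity[sel])
  }, numeric(1))
  ord <- order(fam_id, vapply(copies, `[`, numeric(1), 1))
  tbl <- tibble::tibble(
    family = paste0("F", fam_id),
    copy = paste0("F", fam_id, "_", stats::ave(fam_id, fam_id, FUN = seq_along)),
    start = vapply(copies, `[`, numeric(1), 1),
    end = vapply(copies, `[`, numeric(1), 2),
    strand = ifelse(strand == 1L, "forward", "reverse"),
    identity = mean_idy
  )[ord, ]
  tbl$copy <- paste0(tbl$family,
                     letters[stats::ave(seq_len(nc), tbl$family,
                                        FUN = seq_along)])
  out <- as_repeat_table(tbl, genome_length = G)
  attr(out, "hits") <- hits
  out
}

#' Find short dispersed repeats
#'
#' Same self-comparison as [find_large_repeats()] but reporting hits in the
#' `[min_len, max_len)` bp band, with the fraction of the genome they cover.
#'
#' @inheritParams find_large_repeats
#' @param min_len,max_len Length band in bp (defaults 50 and 999).
#' @return A tibble of hits with attribute `coverage` (fraction of genome
#'   covered by the hit intervals).
#' @export
find_short_repeats <- function(genome, min_len = 50, max_len = 999,
                               min_identity = 0.90, k = 21, max_gap = 50) {
  if (min_len >= max_len) stop("min_len must be < max_len", call. = FALSE)
  hits <- self_hits(genome, k = k, max_gap = max_gap, min_len = min_len,
                    min_identity = min_identity)
  hits <- hits[hits$length >= min_len & hits$length < max_len, ]
  G <- genome$length
  covered <- logical(G)
  for (i in seq_len(nrow(hits))) {
    for (iv in list(c(hits$start_a[i], hits$end_a[i]),
                    c(hits$start_b[i], hits$end_b[i]))) {
      len <- copy_length(iv[1], iv[2], G)
      covered[circ_pos(seq(iv[1], iv[1] + len - 1L), G)] <- TRUE
    }
  }
  attr(hits, "coverage") <- mean(covered)
  hits
}

#' Find tandem repeat arrays
#'
#' Periodicity scan: for each candidate unit length, maximal runs of
#' positions matching the position one unit ahead define tandem arrays.
#' Arrays are reported with their unit length, (possibly fractional) copy
#' number and consensus unit, sorted by start; an array is only reported at
#' its smallest explaining unit.
#'
#' @param genome A [circular_genome()] with sequence.
#' @param min_unit,max_unit Unit length range scanned (defaults 2--100).
#' @param min_span Minimum total array span in bp (default 24).
#' @return A tibble with `start`, `unit_length`, `copy_count`, `span`,
#'   `consensus`.
#' @export
find_tandem_repeats <- function(genome, min_unit = 2, max_unit = 100,
                                min_span = 24) {
  if (is.null(genome$sequence)) stop("genome has no sequence", call. = FALSE)
  G <- genome$length
  x <- charToRaw(paste0(genome$sequence,
                        substr(genome$sequence, 1, min(G, 2L * max_unit))))
  out <- list()
  for (u in seq(min_unit, min(max_unit, G %/% 2))) {
    n <- G # candidate array starts on the circle
    m <- x[seq_len(n + u)] == x[seq_len(n + u) + u]
    m <- m[seq_len(n)]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths >= u)) {
      span <- r$lengths[i] + u
      if (span < min_span) next
      out[[length(out) + 1L]] <- tibble::tibble(
        start = starts[i], unit_length = u,
        copy_count = span / u, span = span,
        consensus = substr(genome$sequence, starts[i], starts[i] + u - 1L)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), unit_length = integer(),
                          copy_count = numeric(), span = integer(),
                          consensus = character()))
  }
  res <- purrr::list_rbind(out)
  res <- res[order(res$start, res$unit_length), ]
  # keep the smallest unit explaining any given span
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    same <- which(res$start >= res$start[i] &
                    res$start + res$span <= res$start[i] + res$span[i])
    same <- setdiff(same, i)
    keep[same[res$unit_length[same] %% res$unit_length[i] == 0]] <- FALSE
  }
  res[keep, ]
}
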