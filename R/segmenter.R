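# ---- segment partitioning of a repeat family --------------------------
#
# A nested repeat family derives from a progenitor copy by end-eliminations
# and occasional replacement of a block by non-homologous sequence. The
# partition of the progenitor into maximal shared blocks (S1...Sk) is
# recovered by projecting every copy's aligned interval onto the reference
# copy and cutting at the union of projected breakpoints.

# best ungapped offset of `qry` against `ref` by k-mer diagonal voting;
# returns the offset o (qry position i aligns to ref position i + o) and
# the per-position match vector over the projected overlap
align_diagonal <- function(qry, ref, k = 15) {
  nq <- nchar(qry); nr <- nchar(ref)
  if (nq < k || nr < k) return(NULL)
  ref_idx <- kmer_index(ref, k)
  qpos <- seq_len(nq - k + 1L)
  qk <- substring(qry, qpos, qpos + k - 1L)
  offs <- integer(0)
  for (i in seq_along(qk)) {
    hits <- ref_idx[[qk[i]]]
    if (!is.null(hits)) offs <- c(offs, hits - qpos[i])
  }
  if (length(offs) == 0) return(NULL)
  o <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
  xq <- charToRaw(qry); xr <- charToRaw(ref)
  q1 <- max(1L, 1L - o); q2 <- min(nq, nr - o)
  if (q2 < q1) return(NULL)
  list(offset = o, q1 = q1, q2 = q2,
       match = xq[q1:q2] == xr[(q1 + o):(q2 + o)])
}

# maximal well-matching interval along a diagonal: positions where a
# centred window of `w` exceeds `floor` identity, trimmed to exact matches
matched_interval <- function(match, w = 31, floor = 0.8) {
  n <- length(match)
  if (n == 0) return(NULL)
  cs <- cumsum(c(0, match))
  half <- w %/% 2
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  dens <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  ok <- which(dens >= floor & match)
  if (length(ok) == 0) return(NULL)
  lo <- min(ok); hi <- max(ok)
  # windowed density trims early near block boundaries: restore the exact
  # match run up to the first true mismatch
  while (hi < n && match[hi + 1L]) hi <- hi + 1L
  while (lo > 1L && match[lo - 1L]) lo <- lo - 1L
  c(lo, hi)
}

#' Partition a repeat family into maximal shared segments
#'
#' Aligns every copy of a family to the reference copy (the longest, by
#' default), projects each copy's aligned span onto the reference, cuts the
#' reference at the union of projected breakpoints, merges blocks shorter
#' than `min_segment` into their neighbours, and detects variant blocks:
#' copy tails that fail to align to the reference but align to each other
#' are reported as variant content (`Sk*`) occupying the adjacent slot.
#'
#' @param x A `repeat_table` (rows of one family, or use `family` to pick).
#' @param genome A [circular_genome()] with sequence.
#' @param family Family id to partition when `x` has several.
#' @param min_segment Merge floor in bp (default 30).
#' @param reference Reference copy id (default: the longest copy).
#' @param identity_floor Identity below which an aligned counterpart is
#'   considered non-homologous (default 0.9).
#' @return An object of class `segment_partition`: list with
#'   `reference_copy`, `segments` (tibble `segment`, `ref_start`,
#'   `ref_end`, `length`), `membership` (named list copy -> content ids)
#'   and `variants` (named character: variant id -> base id).
#' @export
segment_family <- function(x, genome, family = NULL, min_segment = 30,
                           reference = NULL, identity_floor = 0.9) {
  if (!is.null(family)) x <- x[x$family == family, ]
  stopifnot(nrow(x) >= 1, length(unique(x$family)) == 1)
  if (is.null(genome$sequence)) {
    stop("genome has no sequence; supply precomputed segment compositions ",
         "in the repeat table instead", call. = FALSE)
  }
  G <- genome$length
  getseq <- function(i) {
    len <- copy_length(x$start[i], x$end[i], G)
    idx <- circ_pos(seq(x$start[i], x$start[i] + len - 1L), G)
    s <- paste(strsplit(genome$sequence, NULL)[[1]][idx], collapse = "")
    if (x$strand[i] == "reverse") revcomp_chr(s) else s
  }
  ref_i <- if (is.null(reference)) which.max(x$length) else match(reference, x$copy)
  ref_seq <- getseq(ref_i)
  nr <- nchar(ref_seq)

  # project every copy onto the reference
  proj <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    if (i == ref_i) {
      proj[[i]] <- list(r1 = 1L, r2 = nr, q1 = 1L, q2 = nchar(ref_seq),
                        offset = 0L, qlen = nr)
      next
    }
    qs <- getseq(i)
    al <- align_diagonal(qs, ref_seq)
    if (is.null(al)) { proj[[i]] <- NULL; next }
    mi <- matched_interval(al$match, floor = identity_floor)
    if (is.null(mi)) { proj[[i]] <- NULL; next }
    q1 <- al$q1 + mi[1] - 1L; q2 <- al$q1 + mi[2] - 1L
    proj[[i]] <- list(r1 = q1 + al$offset, r2 = q2 + al$offset,
                      q1 = q1, q2 = q2, offset = al$offset, qlen = nchar(qs))
  }

  # breakpoints: aligned-span ends projected onto the reference
  brk <- sort(unique(c(1L, nr + 1L,
                       unlist(lapply(proj, function(p) {
                         if (is.null(p)) NULL else c(p$r1, p$r2 + 1L)
                       })))))
  brk <- brk[brk >= 1L & brk <= nr + 1L]
  # merge blocks shorter than min_segment into the previous block
  keep <- c(TRUE, diff(brk) >= min_segment)
  keep[length(brk)] <- TRUE
  brk <- brk[keep]
  seg_start <- brk[-length(brk)]
  seg_end <- brk[-1] - 1L
  seg_id <- paste0("S", seq_along(seg_start))
  segments <- tibble::tibble(segment = seg_id, ref_start = seg_start,
                             ref_end = seg_end,
                             length = seg_end - seg_start + 1L)

  # membership: blocks inside each copy's aligned span
  membership <- stats::setNames(vector("list", nrow(x)), x$copy)
  tails <- list() # unaligned copy tails, candidates for variant blocks
  for (i in seq_len(nrow(x))) {
    p <- proj[[i]]
    if (is.null(p)) { membership[[i]] <- character(0); next }
    inside <- seg_start >= p$r1 & seg_end <= p$r2
    membership[[i]] <- seg_id[inside]
    if (i != ref_i) {
      qs <- getseq(i)
      if (p$q1 - 1L >= min_segment) {
        tails[[length(tails) + 1L]] <- list(copy = i, side = "left",
                                            seq = substr(qs, 1, p$q1 - 1L))
      }
      if (p$qlen - p$q2 >= min_segment) {
        tails[[length(tails) + 1L]] <- list(copy = i, side = "right",
                                            seq = substr(qs, p$q2 + 1L, p$qlen))
      }
    }
  }

  # variant blocks: tails of two copies that align to each other take the
  # variant id of the reference slot they displace
  variants <- character(0)
  variant_lengths <- numeric(0)
  if (length(tails) >= 2) {
    for (i in seq_len(length(tails) - 1L)) {
      for (j in seq(i + 1L, length(tails))) {
        ta <- tails[[i]]; tb <- tails[[j]]
        if (ta$side != tb$side) next
        al <- align_diagonal(ta$seq, tb$seq)
        if (is.null(al) || mean(al$match) < identity_floor) next
        # the displaced slot: the segment just outside the copy's aligned span
        pi_ <- proj[[ta$copy]]
        slot <- if (ta$side == "right") seg_id[match(pi_$r2 + 1L, seg_start)]
                else seg_id[match(pi_$r1 - 1L, seg_end)]
        if (is.na(slot) || length(slot) == 0) next
        vid <- paste0(slot, "*")
        variants[vid] <- slot
        variant_lengths[vid] <- max(nchar(ta$seq), nchar(tb$seq))
        for (cpi in c(ta$copy, tb$copy)) {
          mem <- membership[[cpi]]
          if (!vid %in% mem) membership[[cpi]] <- c(mem, vid)
        }
      }
    }
  }
  # order each copy's content in reference slot order
  slot_rank <- stats::setNames(seq_along(seg_id), seg_id)
  membership <- lapply(membership, function(mem) {
    base <- sub("\\*$", "", mem)
    mem[order(slot_rank[base])]
  })

  structure(list(family = x$family[1], reference_copy = x$copy[ref_i],
                 segments = segments, membership = membership,
                 variants = variants, variant_lengths = variant_lengths),
            class = "segment_partition")
}

#' Export a segment partition as a segment-length catalog
#'
#' @param partition A `segment_partition`.
#' @return A tibble with columns `family`, `segment`, `length` (base
#'   blocks plus detected variant blocks), usable with
#'   [enumerate_pairs()] and [master_circle()].
#' @export
as_segment_catalog <- function(partition) {
  stopifnot(inherits(partition, "segment_partition"))
  base <- tibble::tibble(family = partition$family,
                         segment = partition$segments$segment,
                         length = partition$segments$length)
  if (length(partition$variant_lengths) > 0) {
    base <- dplyr::bind_rows(base, tibble::tibble(
      family = partition$family,
      segment = names(partition$variant_lengths),
      length = as.integer(partition$variant_lengths)))
  }
  base
}

#' @export
print.segment_partition <- function(x, ...) {
  cat("<segment_partition> family ", x$family, ": ", nrow(x$segments),
      " segment(s) on reference copy ", x$reference_copy, "\n", sep = "")
  invisible(x)
}

#' Tidy a segment partition
#'
#' @param x A `segment_partition`.
#' @param ... Unused.
#' @return A tibble: one row per (copy, segment) membership, with segment
#'   coordinates on the reference copy.
#' @export
tidy.segment_partition <- function(x, ...) {
  purrr::imap(x$membership, function(mem, cp) {
    tibble::tibble(copy = cp, content = mem,
                   segment = sub("\\*$", "", mem),
                   variant = grepl("\\*$", mem))
  }) |>
    purrr::list_rbind() |>
    dplyr::left_join(x$segments, by = "segment")
}

#' Infer the derivation order of repeat copies
#'
#' In nested repeat families the direction of evolution runs from large
#' segment sets to small: a copy whose segment set is a strict subset of
#' another's is taken as its (potential) descendant. Variant content is
#' excluded from the subset test. The edge set is transitively reduced.
#'
#' @param partition A `segment_partition`, or a named list copy -> content
#'   ids.
#' @return A tibble with columns `ancestor`, `descendant`.
#' @export
infer_derivation <- function(partition) {
  membership <- if (inherits(partition, "segment_partition")) {
    partition$membership
  } else partition
  sets <- lapply(membership, function(mem) mem[!grepl("\\*$", mem)])
  cps <- names(sets)
  n <- length(cps)
  adj <- matrix(FALSE, n, n, dimnames = list(cps, cps))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && length(sets[[j]]) > 0 &&
          all(sets[[j]] %in% sets[[i]]) &&
          length(sets[[j]]) < length(sets[[i]])) {
        adj[i, j] <- TRUE
      }
    }
  }
  # transitive reduction (edge sets are a DAG: strict subset relation)
  red <- adj
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j]) {
        for (m in seq_len(n)) {
          if (adj[i, m] && adj[m, j]) red[i, j] <- FALSE
        }
      }
    }
  }
  idx <- which(red, arr.ind = TRUE)
  tibble::tibble(ancestor = cps[idx[, 1]], descendant = cps[idx[, 2]]) |>
    dplyr::arrange(.data$ancestor, .data$descendant)
}

#' Solve segment lengths from copy lengths
#'
#' Each copy's length is the sum of its member segments' lengths, giving a
#' linear system over the unknown segment lengths. Segments whose length is
#' uniquely determined are reported with their value; for the rest, the
#' minimal contiguous runs whose sums are determined are reported as
#' aggregates. Inconsistencies (non-zero least-squares residual) are
#' flagged, not fatal.
#'
#' @param membership Named list copy -> content ids (as in a
#'   `segment_partition`), or a `repeat_table` (with `family`).
#' @param copy_lengths Named numeric: copy -> length bp.
#' @param known Named numeric of known segment lengths (e.g.
#'   `c("S6*" = 673)`), entering the system as extra equations.
#' @param family Family id when `membership` is a `repeat_table`.
#' @param tol Numerical tolerance.
#' @return A list with `segments` (tibble `segment`, `length`,
#'   `determined`), `aggregates` (tibble `segments`, `length`: determined
#'   sums of undetermined runs), `residual` and `consistent`.
#' @export
solve_segment_lengths <- function(membership, copy_lengths, known = NULL,
                                  family = NULL, tol = 1e-8) {
  if (is.data.frame(membership)) {
    tbl <- membership
    if (!is.null(family)) tbl <- tbl[tbl$family == family, ]
    copy_lengths <- stats::setNames(tbl$length, tbl$copy)
    membership <- stats::setNames(tbl$segments, tbl$copy)
  }
  # reference order: slot order of the copy with the most segments
  ref_mem <- membership[[which.max(lengths(membership))]]
  slot_order <- unique(sub("\\*$", "", ref_mem))
  ids <- unique(unlist(membership))
  base <- sub("\\*$", "", ids)
  slot_order <- c(slot_order, setdiff(unique(base), slot_order))
  ids <- ids[order(match(base, slot_order), grepl("\\*$", ids))]
  n <- length(ids)
  rows <- lapply(names(membership), function(cp) {
    as.numeric(ids %in% membership[[cp]])
  })
  A <- do.call(rbind, rows)
  b <- as.numeric(copy_lengths[names(membership)])
  if (!is.null(known)) {
    for (k in names(known)) {
      r <- as.numeric(ids == k)
      if (sum(r) == 1) { A <- rbind(A, r); b <- c(b, known[[k]]) }
    }
  }
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d, 1)
  V <- sv$v[, pos, drop = FALSE]
  x_min <- V %*% (t(sv$u[, pos, drop = FALSE]) %*% b / sv$d[pos])
  P <- V %*% t(V) # projection onto the row space
  determined <- abs(diag(P) - 1) < 1e-6
  residual <- sqrt(sum((A %*% x_min - b)^2))
  segs <- tibble::tibble(
    segment = ids,
    length = ifelse(determined, round(as.numeric(x_min)), NA_real_),
    determined = determined
  )
  # minimal determined contiguous runs of undetermined base segments
  base_ids <- ids[!grepl("\\*$", ids)]
  aggs <- list()
  for (i in seq_along(base_ids)) {
    for (j in seq(i, length(base_ids))) {
      run <- base_ids[i:j]
      if (all(determined[match(run, ids)])) next
      u <- as.numeric(ids %in% run)
      if (sqrt(sum((P %*% u - u)^2)) < 1e-6) {
        aggs[[length(aggs) + 1L]] <- tibble::tibble(
          segments = paste(run, collapse = "+"),
          length = round(sum(x_min[match(run, ids)]))
        )
        break # minimal run starting at i
      }
    }
  }
  list(segments = segs,
       aggregates = if (length(aggs)) purrr::list_rbind(aggs) else
         tibble::tibble(segments = character(), length = numeric()),
       residual = residual,
       consistent = residual < max(1, sum(b)) * 1e-9 + 0.5)
}
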