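# Internal slot model of a repeat family.
#
# Each family has an ordered reference segment system (the slots of its
# longest / most complete copy). A copy occupies a contiguous run of slots,
# and the *content* of a slot is a segment id: usually the reference id, but
# a variant id (e.g. "S6*") when a non-homologous block occupies the slot.
# Homology between two copies holds slot-wise where the content ids match.
family_model <- function(tbl, catalog = NULL, genome = NULL) {
  stopifnot(inherits(tbl, "repeat_table") || is.data.frame(tbl))
  fams <- split(seq_len(nrow(tbl)), tbl$family)
  lapply(fams, function(idx) {
    sub <- tbl[idx, ]
    segs <- sub$segments
    assumed <- all(lengths(segs) == 0)
    if (assumed) segs <- rep(list("WHOLE"), nrow(sub))
    base_of <- function(ids) sub("\\*$", "", ids)
    # reference slot order: from the copy with the most slots (ties: longest)
    ref_i <- order(-lengths(segs), -sub$length)[1]
    slots <- base_of(segs[[ref_i]])
    if (anyDuplicated(slots)) {
      stop("family ", sub$family[1], ": reference copy repeats a segment id",
           call. = FALSE)
    }
    copies <- lapply(seq_len(nrow(sub)), function(i) {
      ids <- segs[[i]]
      pos <- match(base_of(ids), slots)
      if (anyNA(pos)) {
        stop("family ", sub$family[1], ": copy ", sub$copy[i],
             " has segments absent from the reference copy", call. = FALSE)
      }
      if (length(pos) > 0 && !identical(pos, seq(pos[1], pos[length(pos)]))) {
        stop("family ", sub$family[1], ": copy ", sub$copy[i],
             " segments are not contiguous in reference order", call. = FALSE)
      }
      list(copy = sub$copy[i], family = sub$family[1],
           slot_lo = pos[1], slot_hi = pos[length(pos)],
           content = stats::setNames(ids, slots[pos]),
           dir = if (sub$strand[i] == "forward") 1L else -1L,
           start = sub$start[i], end = sub$end[i], length = sub$length[i])
    })
    names(copies) <- sub$copy
    # content lengths: catalog first, else whole-copy fallback
    seg_len <- stats::setNames(integer(0), character(0))
    if (!is.null(catalog)) {
      cat_sub <- catalog[catalog$family == sub$family[1], ]
      seg_len <- stats::setNames(as.integer(cat_sub$length), cat_sub$segment)
    }
    if (assumed) {
      seg_len <- c(seg_len, stats::setNames(min(sub$length), "WHOLE"))
    }
    if (length(slots) == 1 && !slots %in% names(seg_len)) {
      # single-slot family: the slot is the whole copy
      seg_len <- c(seg_len, stats::setNames(min(sub$length), slots))
    }
    orig_sigs <- vapply(copies, function(cp) {
      paste(cp$slot_lo, cp$slot_hi, paste(cp$content, collapse = ","))
    }, character(1))
    list(family = sub$family[1], slots = slots, copies = copies,
         seg_len = seg_len, assumed = assumed, orig_sigs = unname(orig_sigs))
  })
}

seg_length <- function(model, ids) {
  if (length(ids) == 0) return(0L)
  v <- model$seg_len[ids]
  if (anyNA(v)) {
    stop("family ", model$family, ": no catalogued length for segment(s) ",
         paste(ids[is.na(v)], collapse = ", "),
         "; supply a segment catalog", call. = FALSE)
  }
  sum(as.integer(v))
}

# master/circle coordinates of the reference-order boundary before slot k of
# a copy: for a forward copy the first base of slot k; for a reverse copy the
# boundary index just after the base holding the slot-k start.
copy_cut_at_slot <- function(cp, model, k, G) {
  pre <- if (k > cp$slot_lo) cp$content[seq(cp$slot_lo, k - 1) - cp$slot_lo + 1] else character(0)
  off <- seg_length(model, unname(pre))
  if (cp$dir == 1L) circ_pos(cp$start + off, G)
  else circ_pos(cp$end - off + 1L, G)
}

shared_content <- function(cp_a, cp_b) {
  lo <- max(cp_a$slot_lo, cp_b$slot_lo)
  hi <- min(cp_a$slot_hi, cp_b$slot_hi)
  if (lo > hi) return(character(0))
  ks <- seq(lo, hi)
  ca <- unname(cp_a$content[ks - cp_a$slot_lo + 1])
  cb <- unname(cp_b$content[ks - cp_b$slot_lo + 1])
  stats::setNames(ca, ks)[ca == cb]
}

#' Enumerate homologous repeat pairs
#'
#' Every unordered pair of copies from the same family whose shared
#' homologous content totals at least `min_shared` bp forms a recombination
#' substrate: a *direct* pair (equal strands) can mediate fission of the
#' circle into two subgenomic circles, an *inverted* pair (opposite strands)
#' can mediate inversion of the intervening arc. Variant segments (e.g.
#' `S6` vs `S6*`) occupy the same slot but are non-homologous and never count
#' as shared. The recombination anchor is the start of the leftmost shared
#' segment within each copy, mapped to master coordinates.
#'
#' @param x A `repeat_table` tibble (see [read_repeat_table()]).
#' @param genome A [circular_genome()] or genome length in bp.
#' @param catalog Optional segment-length catalog tibble
#'   (see [read_segment_catalog()]); required to place anchors in families
#'   with more than one segment.
#' @param min_shared Minimum total shared homologous bp for a pair to be
#'   reported (default 500).
#' @return A tibble with one row per pair: `family`, `copy_a`, `copy_b`,
#'   `orientation` (`"direct"`/`"inverted"`), list-column `shared`,
#'   `shared_bp`, anchors and cut boundaries on the master, and `assumed`
#'   (`TRUE` when the family had no segment composition and whole-copy
#'   homology was assumed).
#' @examples
#' enumerate_pairs(soybean_mt_repeats(), soybean_mt_genome(),
#'                 soybean_mt_segments())
#' @export
enumerate_pairs <- function(x, genome, catalog = NULL, min_shared = 500) {
  G <- genome_length(genome)
  models <- family_model(x, catalog)
  rows <- purrr::map(models, function(m) {
    cps <- m$copies
    if (length(cps) < 2) return(NULL)
    combos <- utils::combn(names(cps), 2, simplify = FALSE)
    purrr::map(combos, function(ab) {
      ca <- cps[[ab[1]]]; cb <- cps[[ab[2]]]
      sh <- shared_content(ca, cb)
      if (length(sh) == 0) return(NULL)
      bp <- seg_length(m, unname(sh))
      if (bp < min_shared) return(NULL)
      k <- as.integer(names(sh)[1]) # leftmost shared slot
      cut_a <- copy_cut_at_slot(ca, m, k, G)
      cut_b <- copy_cut_at_slot(cb, m, k, G)
      tibble::tibble(
        family = m$family, copy_a = ca$copy, copy_b = cb$copy,
        orientation = if (ca$dir == cb$dir) "direct" else "inverted",
        shared = list(unname(sh)), shared_bp = bp,
        anchor_a = if (ca$dir == 1L) cut_a else circ_pos(cut_a - 1L, G),
        anchor_b = if (cb$dir == 1L) cut_b else circ_pos(cut_b - 1L, G),
        cut_a = cut_a, cut_b = cut_b,
        assumed = m$assumed
      )
    }) |> purrr::compact() |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(
      family = character(), copy_a = character(), copy_b = character(),
      orientation = character(), shared = list(), shared_bp = integer(),
      anchor_a = integer(), anchor_b = integer(),
      cut_a = integer(), cut_b = integer(), assumed = logical()
    )
  }
  out
}
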