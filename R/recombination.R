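# ---- circle structures -------------------------------------------------
#
# A circle is an ordered traversal of signed master-genome intervals
# ("blocks"), plus the repeat-copy instances it carries. Blocks are stored
# as an integer matrix with columns lo, hi, strand (+1/-1); a +1 block is
# traversed lo -> hi, a -1 block hi -> lo. Blocks never wrap the master
# origin: a contiguous master run across the origin appears as two blocks,
# uniformly across all derivations, so canonical keys stay comparable.
#
# Copy instances carry the slot-run model of pairs.R plus their placement in
# circle coordinates: c_ref0 is the circle position of the copy's
# reference-leftmost base, dir the direction in which reference coordinates
# increase along the circle.

new_circle <- function(blocks, copies, size = sum(blocks[, 2] - blocks[, 1] + 1)) {
  structure(list(blocks = blocks, size = as.integer(size), copies = copies),
            class = "circle_structure")
}

#' @export
print.circle_structure <- function(x, ...) {
  cat("<circle_structure> ", format(x$size, big.mark = ","), " bp, ",
      nrow(x$blocks), " block(s), ", length(x$copies),
      " repeat copy instance(s)\n", sep = "")
  invisible(x)
}

#' Build the master circle from a repeat table
#'
#' Constructs the master-circle structure (a single forward block spanning
#' the whole genome) carrying one repeat-copy instance per row of the table,
#' ready for [fission()], [inversion()] and [pool_closure()].
#'
#' @inheritParams enumerate_pairs
#' @return A `circle_structure` object.
#' @examples
#' master_circle(soybean_mt_repeats(), soybean_mt_genome(), soybean_mt_segments())
#' @export
master_circle <- function(x, genome, catalog = NULL) {
  G <- genome_length(genome)
  models <- family_model(x, catalog)
  copies <- list()
  for (m in models) {
    for (cp in m$copies) {
      inst <- list(family = cp$family, label = cp$copy,
                   slot_lo = cp$slot_lo, slot_hi = cp$slot_hi,
                   content = unname(cp$content), dir = cp$dir,
                   c_ref0 = if (cp$dir == 1L) cp$start else cp$end,
                   phys_len = seg_length(m, unname(cp$content)))
      if (!is.na(cp$length) && inst$phys_len != cp$length) {
        warning("family ", m$family, " copy ", cp$copy,
                ": catalogued segment lengths sum to ", inst$phys_len,
                " bp but the table prints ", cp$length, " bp", call. = FALSE)
      }
      copies[[length(copies) + 1L]] <- inst
    }
  }
  circ <- new_circle(matrix(c(1L, G, 1L), nrow = 1,
                            dimnames = list(NULL, c("lo", "hi", "strand"))),
                     copies, size = G)
  attr(circ, "models") <- models
  circ
}

# ---- block arithmetic --------------------------------------------------

block_len <- function(blocks) blocks[, 2] - blocks[, 1] + 1L

# ensure a block boundary exists at circle boundary b (between positions
# b-1 and b); returns the (possibly re-split) block matrix
split_blocks_at <- function(blocks, b, size) {
  b <- circ_pos(b, size)
  lens <- block_len(blocks)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  if (b == 1L) return(blocks)
  i <- findInterval(b, starts) # block containing position b
  if (starts[i] == b) return(blocks)
  o <- b - starts[i] # split after o positions of block i
  blk <- blocks[i, ]
  if (blk[3] == 1L) {
    left <- c(blk[1], blk[1] + o - 1L, 1L)
    right <- c(blk[1] + o, blk[2], 1L)
  } else {
    left <- c(blk[2] - o + 1L, blk[2], -1L)
    right <- c(blk[1], blk[2] - o, -1L)
  }
  out <- rbind(
    if (i > 1) blocks[seq_len(i - 1), , drop = FALSE],
    left, right,
    if (i < nrow(blocks)) blocks[seq(i + 1, nrow(blocks)), , drop = FALSE]
  )
  dimnames(out) <- list(NULL, c("lo", "hi", "strand"))
  out
}

# rotate the block list so the block starting at circle boundary b comes
# first; b must already be a block boundary
rotate_blocks_to <- function(blocks, b, size) {
  b <- circ_pos(b, size)
  lens <- block_len(blocks)
  starts <- cumsum(lens) - lens + 1L
  i <- match(b, starts)
  stopifnot(!is.na(i))
  if (i == 1L) blocks
  else blocks[c(seq(i, nrow(blocks)), seq_len(i - 1)), , drop = FALSE]
}

flip_blocks <- function(blocks) {
  out <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
  out[, 3] <- -out[, 3]
  out
}

# merge cyclically adjacent blocks that continue the same master run in the
# same direction (never across the master origin, by exact +1 arithmetic)
normalize_blocks <- function(blocks) {
  repeat {
    n <- nrow(blocks)
    if (n <= 1) return(blocks)
    merged <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (i == j) next
      a <- blocks[i, ]; b <- blocks[j, ]
      if (a[3] == b[3] &&
          ((a[3] == 1L && b[1] == a[2] + 1L) ||
           (a[3] == -1L && b[2] == a[1] - 1L))) {
        newb <- if (a[3] == 1L) c(a[1], b[2], 1L) else c(b[1], a[2], -1L)
        blocks[i, ] <- newb
        blocks <- blocks[-j, , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(blocks)
  }
}

#' Canonical key of a circular block structure
#'
#' Two circles that are equal up to rotation of the traversal and/or
#' reversal of the whole molecule (strand flip) receive the same key, which
#' is the lexicographically minimal serialization over all rotations of the
#' block list and of its orientation-reversed complement. Runs of blocks
#' that are contiguous on the master are merged first, so the key does not
#' depend on the event history that produced the circle.
#'
#' @param circle A `circle_structure`, or a 3-column block matrix
#'   (`lo`, `hi`, `strand`).
#' @return A single string.
#' @export
canonical_form <- function(circle) {
  blocks <- if (inherits(circle, "circle_structure")) circle$blocks else circle
  blocks <- normalize_blocks(blocks)
  ser <- function(m) {
    paste(paste(m[, 1], m[, 2], m[, 3], sep = ":"), collapse = "|")
  }
  n <- nrow(blocks)
  cands <- character(0)
  for (m in list(blocks, flip_blocks(blocks))) {
    for (r in seq_len(n)) {
      rot <- m[c(seq(r, n), if (r > 1) seq_len(r - 1)), , drop = FALSE]
      cands <- c(cands, ser(rot))
    }
  }
  min(cands)
}

# ---- copy placement helpers -------------------------------------------

copy_span_start <- function(cp, size) {
  if (cp$dir == 1L) cp$c_ref0 else circ_pos(cp$c_ref0 - cp$phys_len + 1L, size)
}

in_arc <- function(p, from, len, size) ((p - from) %% size) < len

# circle-cut boundary before reference slot k of a copy instance
instance_cut_at_slot <- function(cp, model, k, size) {
  pre <- if (k > cp$slot_lo) cp$content[seq_len(k - cp$slot_lo)] else character(0)
  off <- seg_length(model, pre)
  if (cp$dir == 1L) circ_pos(cp$c_ref0 + off, size)
  else circ_pos(cp$c_ref0 - off + 1L, size)
}

# position (not boundary) of the first base of slot k within a copy
instance_base_at_slot <- function(cp, model, k, size) {
  b <- instance_cut_at_slot(cp, model, k, size)
  if (cp$dir == 1L) b else circ_pos(b - 1L, size)
}

shared_content_inst <- function(a, b) {
  lo <- max(a$slot_lo, b$slot_lo)
  hi <- min(a$slot_hi, b$slot_hi)
  if (lo > hi) return(NULL)
  ks <- seq(lo, hi)
  ca <- a$content[ks - a$slot_lo + 1]
  cb <- b$content[ks - b$slot_lo + 1]
  ok <- ca == cb
  if (!any(ok)) return(NULL)
  list(slots = ks[ok], ids = ca[ok])
}

# recombinant copy: slots < k from `lo_parent`, slots >= k from `ge_parent`
hybrid_copy <- function(lo_parent, ge_parent, k, models, size) {
  model <- models[[lo_parent$family]]
  has_lo <- lo_parent$slot_lo < k
  run_lo <- if (has_lo) lo_parent$slot_lo else k
  run_hi <- ge_parent$slot_hi
  content <- c(
    if (has_lo) lo_parent$content[seq_len(k - lo_parent$slot_lo)],
    ge_parent$content[seq(k - ge_parent$slot_lo + 1, run_hi - ge_parent$slot_lo + 1)]
  )
  src <- if (has_lo) lo_parent else ge_parent
  ref0 <- if (has_lo) lo_parent$c_ref0
          else instance_base_at_slot(ge_parent, model, k, size)
  list(family = lo_parent$family,
       label = paste0(lo_parent$label, "/", ge_parent$label),
       slot_lo = run_lo, slot_hi = run_hi, content = content,
       dir = src$dir, c_ref0 = ref0,
       phys_len = seg_length(model, content))
}

# ---- events ------------------------------------------------------------

# Apply a recombination event between copy instances ia and ib of `circle`
# at shared slot k. Direct pairs (equal dir) undergo fission into two
# circles; inverted pairs undergo inversion of the arc between the anchors.
# Returns a list of product circle_structure objects (2 for fission, 1 for
# inversion), or NULL when the event is degenerate (coinciding cuts).
apply_event <- function(circle, ia, ib, k, models) {
  size <- circle$size
  A <- circle$copies[[ia]]; B <- circle$copies[[ib]]
  model <- models[[A$family]]
  cutA <- instance_cut_at_slot(A, model, k, size)
  cutB <- instance_cut_at_slot(B, model, k, size)
  if (cutA == cutB) return(NULL)
  s1 <- as.integer((cutB - cutA) %% size)
  blocks <- split_blocks_at(circle$blocks, cutA, size)
  blocks <- split_blocks_at(blocks, cutB, size)
  blocks <- rotate_blocks_to(blocks, cutA, size)
  lens <- block_len(blocks)
  n_arc1 <- match(s1, cumsum(lens))
  others <- circle$copies[-c(ia, ib)]
  h1 <- hybrid_copy(A, B, k, models, size)
  h2 <- hybrid_copy(B, A, k, models, size)

  # a non-participant copy is destroyed when a cut falls strictly inside its
  # (contiguous) span; hybrids intentionally span a junction and skip this
  is_cut <- function(cp) {
    sp <- copy_span_start(cp, size)
    for (b in c(cutA, cutB)) {
      if (in_arc(circ_pos(b - 1L, size), sp, cp$phys_len, size) &&
          in_arc(b, sp, cp$phys_len, size)) return(TRUE)
    }
    FALSE
  }

  if (A$dir == B$dir) { # fission
    p1_blocks <- blocks[seq_len(n_arc1), , drop = FALSE]
    p2_blocks <- blocks[seq(n_arc1 + 1, nrow(blocks)), , drop = FALSE]
    s2 <- size - s1
    place <- function(cp) {
      # assign by where the reference-origin base lands, remap coordinates
      if (in_arc(cp$c_ref0, cutA, s1, size)) {
        cp$c_ref0 <- circ_pos(((cp$c_ref0 - cutA) %% size) + 1L, s1)
        list(1L, cp)
      } else {
        cp$c_ref0 <- circ_pos(((cp$c_ref0 - cutB) %% size) + 1L, s2)
        list(2L, cp)
      }
    }
    cps1 <- list(); cps2 <- list()
    for (cp in c(Filter(Negate(is_cut), others), list(h1), list(h2))) {
      pl <- place(cp)
      if (pl[[1]] == 1L) cps1[[length(cps1) + 1L]] <- pl[[2]]
      else cps2[[length(cps2) + 1L]] <- pl[[2]]
    }
    list(new_circle(normalize_blocks(p1_blocks), cps1, s1),
         new_circle(normalize_blocks(p2_blocks), cps2, s2))
  } else { # inversion
    arc1 <- blocks[seq_len(n_arc1), , drop = FALSE]
    arc2 <- blocks[seq(n_arc1 + 1, nrow(blocks)), , drop = FALSE]
    new_blocks <- rbind(flip_blocks(arc1), arc2)
    # product coordinates keep their origin at cutA of the parent
    remap <- function(cp) {
      o <- (cp$c_ref0 - cutA) %% size
      if (o < s1) { cp$c_ref0 <- circ_pos(s1 - o, size); cp$dir <- -cp$dir }
      else cp$c_ref0 <- circ_pos(o + 1L, size)
      cp
    }
    cps <- lapply(c(Filter(Negate(is_cut), others), list(h1), list(h2)), remap)
    list(new_circle(normalize_blocks(new_blocks), cps, size))
  }
}

# content signature of a copy instance, for matching against the family's
# original copies (a recombinant whose content equals an original copy is
# functionally that copy)
instance_sig <- function(cp) {
  paste(cp$slot_lo, cp$slot_hi, paste(cp$content, collapse = ","))
}

# all applicable events on a circle: one per unordered copy pair with
# shared homologous content >= min_shared; with hybrid_pairs = FALSE only
# copies whose content matches an original family copy may recombine
enumerate_events <- function(circle, models, min_shared, hybrid_pairs = TRUE) {
  cps <- circle$copies
  if (length(cps) < 2) return(list())
  fam <- vapply(cps, `[[`, character(1), "family")
  out <- list()
  for (f in unique(fam)) {
    idx <- which(fam == f)
    if (length(idx) < 2) next
    model <- models[[f]]
    if (!hybrid_pairs) {
      idx <- idx[vapply(cps[idx], instance_sig, character(1)) %in% model$orig_sigs]
      if (length(idx) < 2) next
    }
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq(a + 1, length(idx))) {
        ia <- idx[a]; ib <- idx[b]
        sh <- shared_content_inst(cps[[ia]], cps[[ib]])
        if (is.null(sh)) next
        if (seg_length(model, sh$ids) < min_shared) next
        out[[length(out) + 1L]] <- list(ia = ia, ib = ib, k = sh$slots[1],
                                        type = if (cps[[ia]]$dir == cps[[ib]]$dir)
                                          "fission" else "inversion")
      }
    }
  }
  out
}

# ---- exported single events -------------------------------------------

find_instance <- function(circle, label) {
  labs <- vapply(circle$copies, `[[`, character(1), "label")
  i <- match(label, labs)
  if (is.na(i)) stop("no repeat copy '", label, "' on this circle", call. = FALSE)
  i
}

event_models <- function(circle, models) {
  if (!is.null(models)) return(models)
  m <- attr(circle, "models")
  if (is.null(m)) stop("supply `models` (or use a circle from master_circle())",
                       call. = FALSE)
  m
}

prepare_event <- function(circle, copy_a, copy_b, models) {
  ia <- find_instance(circle, copy_a)
  ib <- find_instance(circle, copy_b)
  A <- circle$copies[[ia]]; B <- circle$copies[[ib]]
  if (A$family != B$family) stop("copies belong to different families", call. = FALSE)
  sh <- shared_content_inst(A, B)
  if (is.null(sh)) stop("copies share no homologous content", call. = FALSE)
  list(ia = ia, ib = ib, k = sh$slots[1], direct = A$dir == B$dir)
}

#' Fission of a circle across a direct repeat pair
#'
#' Intramolecular crossover between two same-orientation homologous repeat
#' copies splits a circle into two subgenomic circles whose sizes sum
#' exactly to the parent's. Each product carries a recombinant (hybrid)
#' repeat copy at the junction, available for further events.
#'
#' @param circle A `circle_structure` (see [master_circle()]).
#' @param copy_a,copy_b Labels of two copies of the same family present on
#'   the circle, in the same orientation.
#' @param models Family models; taken from the circle when built by
#'   [master_circle()].
#' @return A list of two `circle_structure` products.
#' @examples
#' mc <- master_circle(soybean_mt_repeats(), soybean_mt_genome(),
#'                     soybean_mt_segments())
#' prods <- fission(mc, "R1b", "R1d")
#' vapply(prods, `[[`, integer(1), "size") # 79,933 and 322,625 bp
#' @export
fission <- function(circle, copy_a, copy_b, models = NULL) {
  models <- event_models(circle, models)
  ev <- prepare_event(circle, copy_a, copy_b, models)
  if (!ev$direct) {
    stop("copies are in opposite orientation: an inverted pair mediates ",
         "inversion, not fission", call. = FALSE)
  }
  out <- apply_event(circle, ev$ia, ev$ib, ev$k, models)
  if (is.null(out)) stop("degenerate event: crossover anchors coincide", call. = FALSE)
  out <- lapply(out, function(p) { attr(p, "models") <- models; p })
  out
}

#' Inversion of a circle across an inverted repeat pair
#'
#' Crossover between two opposite-orientation homologous repeat copies
#' reverses the arc between the anchors, producing an isometric circle
#' (same size, rearranged internal order).
#'
#' @inheritParams fission
#' @return A single `circle_structure` of the same size.
#' @examples
#' mc <- master_circle(soybean_mt_repeats(), soybean_mt_genome(),
#'                     soybean_mt_segments())
#' iso <- inversion(mc, "R3a", "R3b")
#' iso$size # 402,558 bp, same as the master
#' @export
inversion <- function(circle, copy_a, copy_b, models = NULL) {
  models <- event_models(circle, models)
  ev <- prepare_event(circle, copy_a, copy_b, models)
  if (ev$direct) {
    stop("copies are in the same orientation: a direct pair mediates ",
         "fission, not inversion", call. = FALSE)
  }
  out <- apply_event(circle, ev$ia, ev$ib, ev$k, models)
  if (is.null(out)) stop("degenerate event: crossover anchors coincide", call. = FALSE)
  attr(out[[1]], "models") <- models
  out[[1]]
}
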