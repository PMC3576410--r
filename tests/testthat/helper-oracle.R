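# Independent sequence-level oracle for the recombination engine.
#
# Circles are plain nucleotide strings; events are literal string surgery:
# a direct repeat pair splits the string at the two copy starts, an
# inverted pair reverse-complements the arc between the forward copy's
# start and the reverse copy's end. Repeat copies are found by exact string
# search on both strands, so this shares no code with the block engine.

revcomp_str <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, NULL)[[1]]), collapse = ""))
}

# canonical form of a circular sequence: lexicographic minimum over all
# rotations of the string and of its reverse complement
canon_seq <- function(s) {
  n <- nchar(s)
  best <- NULL
  for (str in c(s, revcomp_str(s))) {
    dbl <- paste0(str, str)
    for (r in seq_len(n)) {
      cand <- substr(dbl, r, r + n - 1L)
      if (is.null(best) || cand < best) best <- cand
    }
  }
  best
}

# all occurrences of `motif` in circular string s, as list(pos, strand)
find_occurrences <- function(s, motif) {
  n <- nchar(s)
  m <- nchar(motif)
  dbl <- paste0(s, s)
  out <- list()
  for (p in seq_len(n)) {
    if (substr(dbl, p, p + m - 1L) == motif) {
      out[[length(out) + 1L]] <- list(pos = p, strand = 1L)
    }
    if (substr(dbl, p, p + m - 1L) == revcomp_str(motif)) {
      out[[length(out) + 1L]] <- list(pos = p, strand = -1L)
    }
  }
  out
}

# rotate circular string so position p becomes position 1
rot_str <- function(s, p) {
  n <- nchar(s)
  p <- ((p - 1L) %% n) + 1L
  if (p == 1L) s else paste0(substr(s, p, n), substr(s, 1, p - 1L))
}

# one event between two occurrences of the same motif
oracle_event <- function(s, occ_a, occ_b, motif_len) {
  n <- nchar(s)
  if (occ_a$strand == occ_b$strand) {
    # fission: cut before each copy start (in the copy's own orientation)
    cut_of <- function(o) if (o$strand == 1L) o$pos else ((o$pos + motif_len - 1L) %% n) + 1L
    ca <- cut_of(occ_a); cb <- cut_of(occ_b)
    if (ca == cb) return(NULL)
    r <- rot_str(s, ca)
    len1 <- (cb - ca) %% n
    list(substr(r, 1, len1), substr(r, len1 + 1L, n))
  } else {
    fwd <- if (occ_a$strand == 1L) occ_a else occ_b
    rev_ <- if (occ_a$strand == 1L) occ_b else occ_a
    ca <- fwd$pos
    cb <- ((rev_$pos + motif_len - 1L) %% n) + 1L # boundary after the copy
    if (ca == cb) return(NULL)
    r <- rot_str(s, ca)
    len1 <- (cb - ca) %% n
    list(paste0(revcomp_str(substr(r, 1, len1)), substr(r, len1 + 1L, n)))
  }
}

# full closure by string surgery: motifs are the planted repeat unit
# sequences (one per family, exact copies)
oracle_closure <- function(master_seq, motifs, max_iter = 10000) {
  seen <- new.env(parent = emptyenv())
  queue <- list(master_seq)
  seen[[canon_seq(master_seq)]] <- master_seq
  while (length(queue) > 0 && length(ls(seen)) < max_iter) {
    s <- queue[[1]]; queue <- queue[-1]
    for (motif in motifs) {
      occ <- find_occurrences(s, motif)
      if (length(occ) < 2) next
      for (i in seq_len(length(occ) - 1L)) {
        for (j in seq(i + 1L, length(occ))) {
          prods <- oracle_event(s, occ[[i]], occ[[j]], nchar(motif))
          if (is.null(prods)) next
          for (p in prods) {
            if (nchar(p) == 0) next
            key <- canon_seq(p)
            if (is.null(seen[[key]])) {
              seen[[key]] <- p
              queue[[length(queue) + 1L]] <- p
            }
          }
        }
      }
    }
  }
  sort(ls(seen))
}

# render a block-engine circle to its nucleotide string
render_circle <- function(circle, master_seq) {
  paste(vapply(seq_len(nrow(circle$blocks)), function(i) {
    b <- circle$blocks[i, ]
    s <- substr(master_seq, b[1], b[2])
    if (b[3] == -1L) revcomp_str(s) else s
  }, character(1)), collapse = "")
}

rand_seq_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random block circle for canonical-form property tests
random_blocks <- function(n_blocks, G = 1000) {
  pts <- sort(sample.int(G - 1, n_blocks))
  lo <- c(1L, pts + 1L)[seq_len(n_blocks)]
  hi <- c(pts, G)[seq_len(n_blocks)]
  cbind(lo = lo, hi = hi, strand = sample(c(1L, -1L), n_blocks, replace = TRUE))
}

rotate_blocks_r <- function(m, r) {
  n <- nrow(m)
  m[c(seq(r, n), if (r > 1) seq_len(r - 1)), , drop = FALSE]
}

flip_blocks_r <- function(m) {
  out <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  out[, 3] <- -out[, 3]
  out
}
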