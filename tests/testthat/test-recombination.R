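soy_master <- function() {
  master_circle(soybean_mt_repeats(), soybean_mt_genome(), soybean_mt_segments())
}

test_that("fission across R1b-R1d reproduces the published product sizes", {
  prods <- fission(soy_master(), "R1b", "R1d")
  expect_setequal(vapply(prods, `[[`, integer(1), "size"),
                  c(79933L, 322625L))
  # conservation, exact in bp
  expect_equal(sum(vapply(prods, `[[`, integer(1), "size")), 402558L)
})

test_that("the large product supports the published second-round fission", {
  prods <- fission(soy_master(), "R1b", "R1d")
  big <- prods[[which.max(vapply(prods, `[[`, integer(1), "size"))]]
  labs <- vapply(big$copies, `[[`, character(1), "label")
  # the R1d remnant at the junction is a recombinant copy
  expect_true("R1b/R1d" %in% labs)
  prods2 <- fission(big, "R1b/R1d", "R1e")
  expect_setequal(vapply(prods2, `[[`, integer(1), "size"),
                  c(98721L, 223904L))
})

test_that("symmetrically placed identical direct copies split a toy in half", {
  df <- tibble::tibble(family = "F", copy = c("a", "b"),
                       start = c(1, 501), end = c(100, 600),
                       strand = "forward", segments = rep(list("S1"), 2))
  mc <- master_circle(as_repeat_table(df), 1000)
  prods <- fission(mc, "a", "b")
  expect_equal(vapply(prods, `[[`, integer(1), "size"), c(500L, 500L))
})

test_that("fission rejects inverted pairs and inversion rejects direct pairs", {
  mc <- soy_master()
  expect_error(fission(mc, "R3a", "R3b"), "inversion")
  expect_error(inversion(mc, "R1b", "R1d"), "fission")
})

test_that("inversion preserves size and is an involution", {
  mc <- soy_master()
  iso <- inversion(mc, "R3a", "R3b")
  expect_equal(iso$size, 402558L)
  expect_false(canonical_form(iso) == canonical_form(mc))
  # invert again across the same (now recombinant) pair
  labs <- vapply(iso$copies, `[[`, character(1), "label")
  pair <- grep("R3", labs, value = TRUE)
  back <- inversion(iso, pair[1], pair[2])
  expect_equal(canonical_form(back), canonical_form(mc))
})

test_that("inversion preserves the multiset of block base pairs", {
  mc <- soy_master()
  iso <- inversion(mc, "R4a", "R4b")
  pos <- unlist(apply(iso$blocks, 1, function(b) seq(b[1], b[2])))
  expect_equal(sort(pos), 1:402558)
})

test_that("fission conserves size on many random synthetic instances", {
  set.seed(7)
  for (rep in 1:1000) {
    G <- sample(2000:20000, 1)
    len <- sample(100:500, 1)
    s1 <- sample.int(G - 3 * len, 1)
    s2 <- s1 + len + sample.int(G - s1 - 2 * len, 1)
    strand <- sample(c("forward", "reverse"), 1)
    df <- tibble::tibble(family = "F", copy = c("a", "b"),
                         start = c(s1, s2), end = c(s1, s2) + len - 1L,
                         strand = strand, segments = rep(list("S1"), 2))
    mc <- master_circle(as_repeat_table(df), G)
    prods <- fission(mc, "a", "b")
    sizes <- vapply(prods, `[[`, integer(1), "size")
    expect_equal(sum(sizes), G)
    expect_true(all(sizes > 0))
  }
})

test_that("canonical form is invariant under rotation and flip", {
  b <- cbind(lo = c(1, 201), hi = c(100, 300), strand = c(1L, 1L))
  expect_equal(canonical_form(b), canonical_form(rotate_blocks_r(b, 2)))
  expect_equal(canonical_form(b), canonical_form(flip_blocks_r(b)))
  set.seed(11)
  for (i in 1:100) {
    m <- random_blocks(6)
    key <- canonical_form(m)
    m2 <- rotate_blocks_r(m, sample.int(6, 1))
    if (runif(1) < 0.5) m2 <- flip_blocks_r(m2)
    expect_equal(canonical_form(m2), key)
  }
})

test_that("canonical form ignores event-history block splits", {
  # a block split into master-contiguous pieces is the same molecule
  one <- cbind(lo = 1L, hi = 1000L, strand = 1L)
  split_ <- cbind(lo = c(1L, 401L), hi = c(400L, 1000L), strand = c(1L, 1L))
  expect_equal(canonical_form(one), canonical_form(split_))
})

test_that("engine products render to the same sequences as string surgery", {
  set.seed(21)
  G <- 3000
  motif <- rand_seq_test(300)
  seq0 <- rand_seq_test(G)
  # plant a direct pair at 101 and 1601
  substr(seq0, 101, 400) <- motif
  substr(seq0, 1601, 1900) <- motif
  genome <- circular_genome(G, sequence = seq0)
  df <- tibble::tibble(family = "F", copy = c("a", "b"),
                       start = c(101, 1601), end = c(400, 1900),
                       strand = "forward", segments = rep(list("S1"), 2))
  mc <- master_circle(as_repeat_table(df), G)
  prods <- fission(mc, "a", "b")
  expected <- oracle_event(seq0, list(pos = 101, strand = 1L),
                           list(pos = 1601, strand = 1L), 300)
  expect_setequal(vapply(prods, function(p) canon_seq(render_circle(p, seq0)),
                         character(1)),
                  vapply(expected, canon_seq, character(1)))

  # and an inverted pair
  seq1 <- seq0
  substr(seq1, 1601, 1900) <- revcomp_str(motif)
  df$strand <- c("forward", "reverse")
  mci <- master_circle(as_repeat_table(df), G)
  iso <- inversion(mci, "a", "b")
  exp_iso <- oracle_event(seq1, list(pos = 101, strand = 1L),
                          list(pos = 1601, strand = -1L), 300)
  expect_equal(canon_seq(render_circle(iso, seq1)),
               canon_seq(exp_iso[[1]]))
})
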