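test_that("single events on the soybean tables give 10 subcircles and 8 isomers", {
  sp <- single_event_products(soybean_mt_repeats(), soybean_mt_genome(),
                              soybean_mt_segments())
  g <- glance(sp)
  expect_equal(g$n_small_circles, 10L)
  expect_equal(g$n_isomers, 8L)
  expect_equal(g$max_depth, 1L)
})

test_that("an empty repeat table yields an empty pool", {
  df <- as_repeat_table(tibble::tibble(family = character(),
                                       copy = character(), start = integer(),
                                       end = integer(), strand = character()),
                        genome_length = 10000)
  p <- enumerate_pairs(df, 10000)
  expect_equal(nrow(p), 0L)
})

test_that("one direct pair produces exactly two subcircles, at closure too", {
  df <- tibble::tibble(family = "F", copy = c("a", "b"),
                       start = c(101, 1201), end = c(700, 1800),
                       strand = "forward", segments = rep(list("S1"), 2))
  tbl <- as_repeat_table(df)
  g1 <- glance(single_event_products(tbl, 5000))
  expect_equal(g1$n_small_circles, 2L)
  expect_equal(g1$n_isomers, 0L)
  # single homologous unit: closure adds nothing beyond the single events
  gc_ <- glance(pool_closure(tbl, 5000))
  expect_equal(gc_$n_small_circles, 2L)
})

test_that("every alternative-route product is already in the closure pool", {
  # the three two-fission routes through the R1b/R1d/R1e direct pairs
  cl <- pool_closure(soybean_mt_repeats(), soybean_mt_genome(),
                     soybean_mt_segments(), max_events = 2)
  sizes <- tidy(cl)$size
  for (s in c(79933, 98721, 178654, 223904, 303837, 322625)) {
    expect_true(s %in% sizes)
  }
})

test_that("closure equals exhaustive string surgery on toy instances", {
  set.seed(31)
  G <- 2400
  mk_genome <- function(placements) {
    s <- rand_seq_test(G)
    motifs <- character(0)
    rows <- list()
    for (i in seq_along(placements)) {
      pl <- placements[[i]]
      motif <- rand_seq_test(pl$len)
      motifs <- c(motifs, motif)
      for (j in seq_along(pl$at)) {
        at <- pl$at[j]
        ins <- if (pl$strand[j] == "reverse") revcomp_str(motif) else motif
        substr(s, at, at + pl$len - 1L) <- ins
        rows[[length(rows) + 1L]] <- tibble::tibble(
          family = paste0("F", i), copy = paste0("F", i, letters[j]),
          start = at, end = at + pl$len - 1L, strand = pl$strand[j],
          segments = list("S1"))
      }
    }
    list(seq = s, motifs = motifs,
         tbl = as_repeat_table(purrr::list_rbind(rows), genome_length = G))
  }
  cases <- list(
    # two direct pairs on disjoint arcs
    list(list(len = 150, at = c(101, 701), strand = c("forward", "forward")),
         list(len = 150, at = c(1301, 1901), strand = c("forward", "forward"))),
    # one direct + one inverted pair
    list(list(len = 150, at = c(101, 701), strand = c("forward", "forward")),
         list(len = 150, at = c(1301, 1901), strand = c("forward", "reverse"))),
    # three pairs, mixed orientations
    list(list(len = 120, at = c(51, 451), strand = c("forward", "forward")),
         list(len = 120, at = c(851, 1251), strand = c("forward", "reverse")),
         list(len = 120, at = c(1651, 2051), strand = c("reverse", "reverse")))
  )
  for (case in cases) {
    inst <- mk_genome(case)
    cl <- pool_closure(inst$tbl, G, min_shared = 100)
    engine_keys <- sort(vapply(cl$members$circle, function(circ) {
      canon_seq(render_circle(circ, inst$seq))
    }, character(1)))
    oracle_keys <- oracle_closure(inst$seq, inst$motifs)
    expect_equal(engine_keys, oracle_keys)
  }
})

test_that("closure counts on simulated configs match analytic expectations", {
  cfg <- soybean_like_config()
  sim <- simulate_genome(cfg, seed = 5)
  sp <- single_event_products(sim$repeats, sim$genome$length, sim$catalog)
  g <- glance(sp)
  expect_equal(g$n_small_circles, sim$expected$n_subcircles)
  expect_equal(g$n_isomers, sim$expected$n_isomers)
})

test_that("truncation is flagged when the event budget is exceeded", {
  cl <- pool_closure(soybean_mt_repeats(), soybean_mt_genome(),
                     soybean_mt_segments(), max_circles = 50)
  expect_true(cl$truncated)
  expect_true(glance(cl)$truncated)
})

test_that("gene dispersion reports per-circle gene content", {
  genes <- tibble::tibble(
    gene = c("atp6", "atp1", "nad4L"),
    start = c(63000, 178000, 141000),
    end = c(63900, 179500, 141800),
    class = c("complex_V", "complex_V", "complex_I"))
  sp <- single_event_products(soybean_mt_repeats(), soybean_mt_genome(),
                              soybean_mt_segments())
  disp <- pool_gene_dispersion(sp, genes)
  expect_true(all(c("content", "dispersion") %in% names(disp)))
  master_row <- disp$content[disp$content$size == 402558 &
                               disp$content$gene == "atp6", ]
  expect_true(all(master_row$present[1]))
})
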