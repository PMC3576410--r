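test_that("an exact planted duplication is recovered as one forward family", {
  set.seed(41)
  G <- 50000
  s <- rand_seq_test(G)
  motif <- rand_seq_test(2000)
  substr(s, 5001, 7000) <- motif
  substr(s, 30001, 32000) <- motif
  g <- circular_genome(G, sequence = s)
  tbl <- find_large_repeats(g)
  expect_equal(length(unique(tbl$family)), 1L)
  expect_equal(nrow(tbl), 2L)
  expect_true(all(tbl$strand == "forward"))
  expect_true(all(abs(sort(tbl$start) - c(5001, 30001)) <= 5))
  expect_true(all(abs(tbl$length - 2000) <= 10))
  expect_true(all(tbl$identity >= 0.999))
})

test_that("an inverted diverged duplicate is found with its identity", {
  set.seed(43)
  G <- 40000
  s <- rand_seq_test(G)
  motif <- rand_seq_test(1500)
  diverged <- local({
    v <- strsplit(motif, NULL)[[1]]
    hit <- which(runif(length(v)) < 0.05)
    for (i in hit) v[i] <- sample(setdiff(c("A","C","G","T"), v[i]), 1)
    paste(v, collapse = "")
  })
  substr(s, 2001, 3500) <- motif
  substr(s, 20001, 21500) <- revcomp_str(diverged)
  g <- circular_genome(G, sequence = s)
  tbl <- find_large_repeats(g)
  expect_equal(nrow(tbl), 2L)
  expect_setequal(tbl$strand, c("forward", "reverse"))
  hits <- attr(tbl, "hits")
  expect_true(all(abs(hits$identity - 0.95) <= 0.02))
})

test_that("an origin-spanning repeat copy is found on the doubled scan", {
  set.seed(47)
  G <- 30000
  s <- rand_seq_test(G)
  motif <- rand_seq_test(1200)
  substr(s, 10001, 11200) <- motif
  # second copy wraps the origin: last 600 bp + first 600 bp
  substr(s, G - 599, G) <- substr(motif, 1, 600)
  substr(s, 1, 600) <- substr(motif, 601, 1200)
  g <- circular_genome(G, sequence = s)
  tbl <- find_large_repeats(g)
  expect_equal(nrow(tbl), 2L)
  wrapped <- tbl[tbl$end < tbl$start, ]
  expect_equal(nrow(wrapped), 1L)
  expect_equal(wrapped$length, 1200L, tolerance = 0.01)
})

test_that("genomes without long duplications yield no large repeats", {
  set.seed(53)
  g <- circular_genome(20000, sequence = rand_seq_test(20000))
  tbl <- find_large_repeats(g)
  expect_equal(nrow(tbl), 0L)
})

test_that("planted short repeats are recovered with their genome coverage", {
  set.seed(59)
  cfg <- sim_config(genome_length = 50000,
                    short_repeats = list(count = 20, length = 200))
  sim <- simulate_genome(cfg, seed = 59)
  hits <- find_short_repeats(sim$genome)
  # every planted interval is covered by some hit interval
  covered <- vapply(seq_len(nrow(sim$short)), function(i) {
    any((hits$start_a <= sim$short$start[i] + 5 &
           hits$end_a >= sim$short$end[i] - 5) |
          (hits$start_b <= sim$short$start[i] + 5 &
             hits$end_b >= sim$short$end[i] - 5))
  }, logical(1))
  expect_true(all(covered))
  # coverage close to the analytic planted fraction 20*200/50000
  expect_equal(attr(hits, "coverage"), 20 * 200 / 50000, tolerance = 0.25)
})

test_that("short-repeat length band is validated", {
  g <- circular_genome(1000, sequence = rand_seq_test(1000))
  expect_error(find_short_repeats(g, min_len = 500, max_len = 400), "min_len")
})

test_that("a planted tandem array is recovered with unit and copy number", {
  set.seed(61)
  s <- rand_seq_test(10000)
  substr(s, 2001, 2012) <- "ACGTACGTACGT"
  g <- circular_genome(10000, sequence = s)
  res <- find_tandem_repeats(g, min_span = 12)
  hit <- res[res$start >= 1995 & res$start <= 2001, ]
  expect_gte(nrow(hit), 1L)
  expect_true(any(hit$unit_length == 4 & hit$copy_count >= 3))
})

test_that("random sequence carries no arrays above the span threshold", {
  set.seed(67)
  g <- circular_genome(10000, sequence = rand_seq_test(10000))
  res <- find_tandem_repeats(g, min_span = 24)
  # brute-force oracle: scan every unit length over the same sequence
  brute <- 0L
  x <- strsplit(g$sequence, NULL)[[1]]
  for (u in 2:12) {
    m <- x[1:(10000 - u)] == x[(1 + u):10000]
    r <- rle(m)
    brute <- brute + sum(r$values & (r$lengths + u) >= 24 & r$lengths >= u)
  }
  expect_equal(nrow(res), brute)
})

test_that("a planted 15-bp x 4 array is recovered", {
  set.seed(71)
  cfg <- sim_config(genome_length = 20000,
                    tandem = list(list(unit = 15, copies = 4)))
  sim <- simulate_genome(cfg, seed = 71)
  res <- find_tandem_repeats(sim$genome)
  planted <- sim$tandem
  hit <- res[abs(res$start - planted$start) <= 2, ]
  expect_gte(nrow(hit), 1L)
  expect_true(any(hit$unit_length == 15 | 15 %% hit$unit_length == 0))
})

test_that("detection is invariant under rotating the circle origin", {
  set.seed(73)
  G <- 30000
  s <- rand_seq_test(G)
  motif <- rand_seq_test(1500)
  substr(s, 4001, 5500) <- motif
  substr(s, 17001, 18500) <- motif
  shift <- 12345L
  s_rot <- paste0(substr(s, shift + 1L, G), substr(s, 1, shift))
  t1 <- find_large_repeats(circular_genome(G, sequence = s))
  t2 <- find_large_repeats(circular_genome(G, sequence = s_rot))
  expect_equal(nrow(t1), nrow(t2))
  back <- sort(((t2$start + shift - 1L) %% G) + 1L)
  expect_true(all(abs(back - sort(t1$start)) <= 5))
})
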