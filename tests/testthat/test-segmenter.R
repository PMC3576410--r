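test_that("the copy-length system reproduces the published aggregates", {
  sol <- solve_segment_lengths(soybean_mt_repeats(), family = "R1",
                               known = c("S6*" = 673))
  segs <- sol$segments
  expect_true(sol$consistent)
  # S1 and S2 are individually underdetermined by the system
  expect_false(segs$determined[segs$segment == "S1"])
  expect_false(segs$determined[segs$segment == "S2"])
  aggs <- setNames(sol$aggregates$length, sol$aggregates$segments)
  expect_equal(unname(aggs["S1+S2"]), 4905)
  expect_equal(unname(aggs["S3+S4"]), 1597)
  expect_equal(unname(aggs["S4+S5"]), 2817)
})

test_that("a single copy equals a single fully determined segment", {
  sol <- solve_segment_lengths(list(only = "S1"), c(only = 1234))
  expect_equal(sol$segments$length, 1234)
  expect_true(sol$segments$determined)
})

test_that("a fully determined synthetic system is solved exactly", {
  truth <- c(S1 = 300, S2 = 450, S3 = 120)
  membership <- list(a = c("S1", "S2", "S3"), b = c("S1"), c = c("S2"),
                     d = c("S2", "S3"))
  lens <- vapply(membership, function(m) sum(truth[m]), numeric(1))
  sol <- solve_segment_lengths(membership, lens)
  expect_true(all(sol$segments$determined))
  expect_equal(setNames(sol$segments$length, sol$segments$segment),
               as.numeric(truth), ignore_attr = TRUE)
})

test_that("inconsistent copy lengths are flagged, not fatal", {
  sol <- solve_segment_lengths(list(a = "S1", b = "S1"),
                               c(a = 100, b = 180))
  expect_false(sol$consistent)
  expect_gt(sol$residual, 10)
})

test_that("the shipped soybean catalog satisfies every copy-length equation", {
  cat_ <- soybean_mt_segments()
  tbl <- soybean_mt_repeats()
  lens <- setNames(cat_$length, paste(cat_$family, cat_$segment))
  for (i in seq_len(nrow(tbl))) {
    ids <- paste(tbl$family[i], tbl$segments[[i]])
    expect_equal(unname(sum(lens[ids])), tbl$length[i])
  }
})

test_that("segmentation recovers planted boundaries and variant blocks", {
  cfg <- soybean_like_config()
  sim <- simulate_genome(cfg, seed = 12)
  part <- segment_family(sim$repeats, sim$genome, family = "R1")
  expect_equal(part$reference_copy, "R1e")
  truth <- cfg$families[[1]]$segment_lengths
  # S6 and S7 are never separated by any copy's end: recovered as one block
  expected_lengths <- c(truth[c("S1", "S2", "S3", "S4", "S5")],
                        truth["S6"] + truth["S7"])
  expect_equal(part$segments$length, unname(as.integer(expected_lengths)))
  # membership matches the planted compositions (S6/S7 merged as last block)
  expect_equal(part$membership$R1d, c("S1", "S2", "S3", "S4"))
  expect_equal(part$membership$R1a, c("S3", "S4", "S5", "S6"))
  expect_equal(part$membership$R1b, c("S2", "S3", "S4", "S5", "S6*"))
  expect_equal(part$membership$R1c, c("S4", "S5", "S6*"))
  expect_equal(part$variants, c("S6*" = "S6"))
})

test_that("two identical full-length copies give a single shared segment", {
  set.seed(83)
  cfg <- sim_config(genome_length = 20000, families = list(list(
    family = "T", segment_lengths = c(S1 = 1500),
    copies = list(list(copy = "Ta", from = "S1", to = "S1", strand = "forward"),
                  list(copy = "Tb", from = "S1", to = "S1", strand = "forward"))
  )))
  sim <- simulate_genome(cfg, seed = 83)
  part <- segment_family(sim$repeats, sim$genome, family = "T")
  expect_equal(nrow(part$segments), 1L)
  expect_equal(lengths(part$membership), c(Ta = 1L, Tb = 1L))
})

test_that("segmentation is stable under re-running", {
  cfg <- soybean_like_config()
  sim <- simulate_genome(cfg, seed = 12)
  p1 <- segment_family(sim$repeats, sim$genome, family = "R1")
  p2 <- segment_family(sim$repeats, sim$genome, family = "R1")
  expect_identical(p1$segments, p2$segments)
  expect_identical(p1$membership, p2$membership)
})

test_that("derivation edges follow strict segment-subset relations", {
  cfg <- soybean_like_config()
  sim <- simulate_genome(cfg, seed = 12)
  part <- segment_family(sim$repeats, sim$genome, family = "R1")
  d <- infer_derivation(part)
  expect_true(all(c("R1a", "R1b", "R1d") %in%
                    d$descendant[d$ancestor == "R1e"]))
  expect_true("R1c" %in% d$descendant[d$ancestor == "R1b"])
  # R1e, the progenitor, is never a descendant
  expect_false("R1e" %in% d$descendant)
})

test_that("identical copies produce no derivation edges", {
  d <- infer_derivation(list(a = c("S1", "S2"), b = c("S1", "S2")))
  expect_equal(nrow(d), 0L)
})

test_that("a strictly nested chain reduces to a path", {
  # brute-force subset lattice: a > b > c gives exactly the two cover edges
  d <- infer_derivation(list(a = c("S1", "S2", "S3"), b = c("S1", "S2"),
                             c = "S1"))
  expect_equal(nrow(d), 2L)
  expect_setequal(paste(d$ancestor, d$descendant), c("a b", "b c"))
})

test_that("tidying a partition joins membership with segment coordinates", {
  cfg <- soybean_like_config()
  sim <- simulate_genome(cfg, seed = 12)
  part <- segment_family(sim$repeats, sim$genome, family = "R1")
  td <- tidy(part)
  expect_true(all(c("copy", "content", "segment", "variant",
                    "ref_start", "ref_end") %in% names(td)))
  expect_true(all(td$variant == grepl("\\*$", td$content)))
})
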