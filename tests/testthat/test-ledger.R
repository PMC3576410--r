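test_that("published composition rows reproduce to printed precision", {
  feats <- soybean_mt_features()
  # the nuclear-shared row is arithmetically inconsistent in the published
  # table (its bp and percent disagree); the consistent rows are checked
  feats <- feats[feats$category != "nuclear_shared", ]
  G <- 402558
  # build non-overlapping tracks with exactly the published bp totals
  pos <- 1L
  rows <- list()
  for (i in seq_len(nrow(feats))) {
    rows[[i]] <- tibble::tibble(category = feats$category[i], start = pos,
                                end = pos + feats$bp[i] - 1L)
    pos <- pos + feats$bp[i]
  }
  led <- build_ledger(G, purrr::list_rbind(rows), residual = "unclassified")
  pct <- setNames(led$percent_printed, led$category)
  expect_equal(unname(pct["protein_exon"]), 8.48)
  expect_equal(unname(pct["cis_intron"]), 8.09)
  expect_equal(unname(pct["rRNA"]), 1.31)
  expect_equal(unname(pct["tRNA"]), 0.35)
  expect_equal(unname(pct["chloroplast_like"]), 1.76)
  expect_equal(unname(pct["nuclear_like"]), 1.69)
  expect_equal(round(pct[["mitochondrial_like"]], 1), 57.2)
  expect_equal(unname(pct["bacterial_mitovirus_like"]), 0.26)
  expect_equal(unname(pct["unknown"]), 10.15)
})

test_that("with no tracks the whole genome is unknown", {
  led <- build_ledger(10000, tibble::tibble(category = character(),
                                            start = integer(),
                                            end = integer()))
  expect_equal(led$bp[led$category == "unknown"], 10000L)
  expect_equal(led$percent[led$category == "unknown"], 100)
})

test_that("ledger conserves every position under overlapping tracks", {
  # brute-force per-position oracle on a 1-kb toy with a 100-bp overlap
  G <- 1000
  tracks <- tibble::tibble(
    category = c("protein_exon", "mitochondrial_like"),
    start = c(101, 501), end = c(600, 1000))
  led <- build_ledger(G, tracks)
  expect_equal(sum(led$bp), G)
  oracle <- rep("unknown", G)
  oracle[501:1000] <- "mitochondrial_like"
  oracle[101:600] <- "protein_exon" # higher priority claims the overlap
  for (cat in unique(oracle)) {
    expect_equal(led$bp[led$category == cat], sum(oracle == cat))
  }
})

test_that("conservation holds on random track sets", {
  set.seed(91)
  for (i in 1:20) {
    G <- sample(500:3000, 1)
    n <- sample(1:6, 1)
    s <- sample.int(G - 50, n, replace = TRUE)
    tracks <- tibble::tibble(
      category = sample(c("protein_exon", "rRNA", "nuclear_like"), n,
                        replace = TRUE),
      start = s, end = pmin(G, s + sample(10:400, n, replace = TRUE)))
    led <- build_ledger(G, tracks)
    expect_equal(sum(led$bp), G)
  }
})

test_that("out-of-range intervals name the offending track", {
  expect_error(build_ledger(1000, tibble::tibble(category = "rRNA",
                                                 start = 900, end = 1100)),
               "rRNA")
})

test_that("identical positions give a near-zero uniformity p-value", {
  res <- ks_uniformity(rep(5000, 50), 100000)
  expect_lt(res$p_value, 1e-6)
  res_lin <- ks_uniformity(rep(5000, 50), 100000, circular = FALSE)
  expect_lt(res_lin$p_value, 1e-6)
})

test_that("perfectly uniform quantiles give a minimal statistic", {
  n <- 20
  G <- 10000
  pos <- (seq_len(n) - 0.5) / n * G
  expect_lte(ks_uniformity(pos, G)$statistic, 1 / n + 1e-9)
  expect_lte(ks_uniformity(pos, G, circular = FALSE)$statistic, 1 / n + 1e-9)
})

test_that("circular uniformity is rotation invariant, linear is not", {
  set.seed(97)
  G <- 50000
  pos <- sort(runif(40, 0, G))
  base <- ks_uniformity(pos, G)
  for (shift in c(1000, 12345, 40000)) {
    rot <- (pos + shift) %% G
    res <- ks_uniformity(rot, G)
    expect_equal(res$statistic, base$statistic, tolerance = 1e-10)
    expect_equal(res$p_value, base$p_value, tolerance = 1e-10)
  }
})

test_that("fewer than five positions is an error", {
  expect_error(ks_uniformity(c(1, 2, 3, 4), 100), "at least 5")
})
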