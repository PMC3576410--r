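#' Run the full multipartite-structure analysis
#'
#' Orchestrates the analysis stages in their natural order: repeat
#' discovery (when a sequence is available) or the supplied repeat table;
#' pair enumeration; segment-length solving; single-event products;
#' recombination closure (with the count of sub-master circles reported
#' under every enumeration-semantics switch); composition ledger and
#' uniformity test when tracks/positions are supplied. Table-driven mode
#' (no sequence) is first-class: the printed repeat annotation alone
#' determines the headline combinatorics.
#'
#' @param repeats A `repeat_table`, a path to one, or `NULL` to detect
#'   repeats from the genome sequence.
#' @param genome A [circular_genome()], a genome length in bp, or a FASTA
#'   path.
#' @param catalog Optional segment catalog (tibble or TSV path).
#' @param tracks Optional annotation tracks for [build_ledger()].
#' @param positions Optional positions (bp) for [ks_uniformity()].
#' @param min_len,min_identity Repeat-detection thresholds.
#' @param min_shared Pairing threshold in bp.
#' @param max_events,inversion_scope,hybrid_pairs,max_inversions,max_circles
#'   Closure semantics switches, passed to [pool_closure()]. The default
#'   reading --- each isometric master isomer (one inversion) generating
#'   subgenomic circles through unrestricted fission cascades --- is the
#'   one enumeration of the pool that reaches a fixpoint on rich repeat
#'   systems; see the package vignette.
#' @param semantics_grid Also compute the small-circle count under a grid
#'   of alternative enumeration readings (bounded at `grid_depth` events
#'   for the non-terminating ones).
#' @param grid_depth Event bound used inside the semantics grid.
#' @param out_dir If given, write the report (JSON + TSVs) there.
#' @return A list of class `mtpool_report`.
#' @export
run_full_analysis <- function(repeats = NULL, genome = NULL, catalog = NULL,
                              tracks = NULL, positions = NULL,
                              min_len = 1000, min_identity = 0.90,
                              min_shared = 500,
                              max_events = Inf,
                              inversion_scope = "master_only",
                              hybrid_pairs = TRUE,
                              max_inversions = 1,
                              max_circles = 100000,
                              semantics_grid = FALSE, grid_depth = 4,
                              out_dir = NULL) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.numeric(genome)) genome <- circular_genome(genome)
  if (is.character(repeats)) {
    repeats <- read_repeat_table(repeats, genome_length = genome$length)
  }
  if (is.character(catalog)) catalog <- read_segment_catalog(catalog)
  if (is.null(repeats)) {
    if (is.null(genome$sequence)) {
      stop("supply either a repeat table or a genome with sequence",
           call. = FALSE)
    }
    repeats <- find_large_repeats(genome, min_len = min_len,
                                  min_identity = min_identity)
  }
  stopifnot(inherits(genome, "circular_genome"))

  pairs <- enumerate_pairs(repeats, genome, catalog, min_shared = min_shared)

  seg_solutions <- lapply(split(seq_len(nrow(repeats)), repeats$family),
                          function(idx) {
    sub <- repeats[idx, ]
    if (all(lengths(sub$segments) <= 1)) return(NULL)
    kn <- NULL
    if (!is.null(catalog)) {
      cat_sub <- catalog[catalog$family == sub$family[1] &
                           grepl("\\*$", catalog$segment), ]
      if (nrow(cat_sub) > 0) kn <- setNames(cat_sub$length, cat_sub$segment)
    }
    solve_segment_lengths(sub, family = sub$family[1], known = kn)
  })
  seg_solutions <- purrr::compact(seg_solutions)

  single <- if (nrow(pairs) > 0) {
    single_event_products(repeats, genome, catalog, min_shared = min_shared)
  } else NULL
  pool <- if (nrow(pairs) > 0) {
    pool_closure(repeats, genome, catalog, min_shared = min_shared,
                 max_events = max_events, max_circles = max_circles,
                 inversion_scope = inversion_scope,
                 hybrid_pairs = hybrid_pairs,
                 max_inversions = max_inversions)
  } else NULL

  grid <- NULL
  if (semantics_grid && nrow(pairs) > 0) {
    readings <- list(
      list(name = "single_events", max_events = 1,
           inversion_scope = "everywhere", hybrid_pairs = TRUE,
           max_inversions = Inf),
      list(name = "fission_cascades_master", max_events = Inf,
           inversion_scope = "never", hybrid_pairs = TRUE,
           max_inversions = 0),
      list(name = "isomers_plus_fission_cascades", max_events = Inf,
           inversion_scope = "master_only", hybrid_pairs = TRUE,
           max_inversions = 1),
      list(name = "annotated_pairs_only_depth_bounded", max_events = grid_depth,
           inversion_scope = "everywhere", hybrid_pairs = FALSE,
           max_inversions = Inf),
      list(name = "full_closure_depth_bounded", max_events = grid_depth,
           inversion_scope = "everywhere", hybrid_pairs = TRUE,
           max_inversions = Inf)
    )
    grid <- purrr::map(readings, function(r) {
      cl <- pool_closure(repeats, genome, catalog, min_shared = min_shared,
                         max_events = r$max_events,
                         max_circles = max_circles,
                         inversion_scope = r$inversion_scope,
                         hybrid_pairs = r$hybrid_pairs,
                         max_inversions = r$max_inversions)
      g <- glance(cl)
      tibble::tibble(reading = r$name,
                     inversion_scope = r$inversion_scope,
                     hybrid_pairs = r$hybrid_pairs,
                     max_inversions = r$max_inversions,
                     max_events = r$max_events,
                     n_small_circles = g$n_small_circles,
                     n_isomers = g$n_isomers,
                     truncated = g$truncated)
    }) |> purrr::list_rbind()
  }

  ledger <- if (!is.null(tracks)) build_ledger(genome, tracks) else NULL
  ks <- if (!is.null(positions)) ks_uniformity(positions, genome) else NULL

  report <- structure(list(
    genome = list(name = genome$name, length = genome$length,
                  has_sequence = !is.null(genome$sequence)),
    repeats = repeats,
    pairs = pairs,
    n_pairs = nrow(pairs),
    n_direct = sum(pairs$orientation == "direct"),
    n_inverted = sum(pairs$orientation == "inverted"),
    segment_solutions = seg_solutions,
    single_events = if (!is.null(single)) glance(single) else NULL,
    pool = if (!is.null(pool)) glance(pool) else NULL,
    pool_members = if (!is.null(pool)) tidy(pool) else NULL,
    closure_semantics = grid,
    ledger = ledger,
    ks = ks,
    params = list(min_len = min_len, min_identity = min_identity,
                  min_shared = min_shared, max_events = max_events,
                  inversion_scope = inversion_scope,
                  hybrid_pairs = hybrid_pairs,
                  max_inversions = max_inversions)
  ), class = "mtpool_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mtpool_report <- function(x, ...) {
  cat("<mtpool_report> genome ", x$genome$name, " (",
      format(x$genome$length, big.mark = ","), " bp)\n", sep = "")
  cat("  repeat copies: ", nrow(x$repeats), " in ",
      length(unique(x$repeats$family)), " families\n", sep = "")
  cat("  pairs: ", x$n_pairs, " (", x$n_direct, " direct, ", x$n_inverted,
      " inverted)\n", sep = "")
  if (!is.null(x$single_events)) {
    cat("  single-event products: ", x$single_events$n_small_circles,
        " subgenomic circles, ", x$single_events$n_isomers, " isomers\n",
        sep = "")
  }
  if (!is.null(x$pool)) {
    cat("  pool closure: ", x$pool$n_small_circles, " small circles, ",
        x$pool$n_isomers, " isomers",
        if (x$pool$truncated) " [truncated]", "\n", sep = "")
  }
  if (!is.null(x$closure_semantics)) {
    cat("  small-circle count under each enumeration semantics:\n")
    print(x$closure_semantics)
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_repeat_table(report$repeats, file.path(out_dir, "repeats.tsv"))
  readr::write_tsv(dplyr::select(report$pairs, -"shared"),
                   file.path(out_dir, "pairs.tsv"), progress = FALSE)
  if (!is.null(report$pool_members)) {
    readr::write_tsv(report$pool_members, file.path(out_dir, "pool.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$ledger)) {
    readr::write_tsv(tibble::as_tibble(report$ledger),
                     file.path(out_dir, "ledger.tsv"), progress = FALSE)
  }
  summary <- list(
    genome = report$genome,
    n_pairs = report$n_pairs, n_direct = report$n_direct,
    n_inverted = report$n_inverted,
    single_events = report$single_events,
    pool = report$pool,
    closure_semantics = report$closure_semantics,
    ks = report$ks,
    params = report$params
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
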