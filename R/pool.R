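# ---- the molecular pool ------------------------------------------------

new_structure_pool <- function(members, genome_length, truncated, params) {
  structure(list(members = members, genome_length = genome_length,
                 truncated = truncated, params = params),
            class = "structure_pool")
}

#' @export
print.structure_pool <- function(x, ...) {
  g <- glance(x)
  cat("<structure_pool> ", g$n_circles, " distinct circle(s): ",
      g$n_small_circles, " subgenomic (< master size), ",
      g$n_isomers, " isometric master isomer(s)",
      if (x$truncated) " [truncated]", "\n", sep = "")
  invisible(x)
}

pool_engine <- function(master, models, min_shared, max_events, max_circles,
                        inversion_scope = c("everywhere", "master_only", "never"),
                        hybrid_pairs = TRUE, max_inversions = Inf) {
  inversion_scope <- match.arg(inversion_scope)
  G <- master$size
  visited <- new.env(parent = emptyenv(), hash = TRUE)
  members <- vector("list", 256)
  n_mem <- 0L
  add <- function(circ, depth, parent, event, n_inv) {
    key <- canonical_form(circ$blocks)
    if (!is.null(visited[[key]])) return(NULL)
    visited[[key]] <- TRUE
    n_mem <<- n_mem + 1L
    if (n_mem > length(members)) length(members) <<- 2L * n_mem
    members[[n_mem]] <<- list(key = key, size = circ$size,
                              n_blocks = nrow(circ$blocks), depth = depth,
                              parent = parent, event = event,
                              n_inv = n_inv, circle = circ)
    n_mem
  }
  add(master, 0L, NA_character_, NA_character_, 0L)
  queue <- list(1L)
  head <- 1L
  truncated <- FALSE
  while (head <= length(queue)) {
    i <- queue[[head]]; head <- head + 1L
    rec <- members[[i]]
    if (rec$depth >= max_events) next
    circ <- rec$circle
    for (ev in enumerate_events(circ, models, min_shared, hybrid_pairs)) {
      if (ev$type == "inversion" &&
          (inversion_scope == "never" ||
           rec$n_inv >= max_inversions ||
           (inversion_scope == "master_only" && circ$size < G))) next
      prods <- apply_event(circ, ev$ia, ev$ib, ev$k, models)
      if (is.null(prods)) next
      lab <- paste0(ev$type, ":",
                    circ$copies[[ev$ia]]$label, "-", circ$copies[[ev$ib]]$label)
      for (p in prods) {
        j <- add(p, rec$depth + 1L, rec$key, lab,
                 rec$n_inv + (ev$type == "inversion"))
        if (!is.null(j)) {
          if (n_mem >= max_circles) { truncated <- TRUE; break }
          queue[[length(queue) + 1L]] <- j
        }
      }
      if (truncated) break
    }
    if (truncated) break
  }
  members <- members[seq_len(n_mem)]
  tbl <- tibble::tibble(
    key = vapply(members, `[[`, character(1), "key"),
    size = vapply(members, `[[`, integer(1), "size"),
    n_blocks = vapply(members, `[[`, integer(1), "n_blocks"),
    depth = vapply(members, `[[`, integer(1), "depth"),
    n_inversions = vapply(members, function(m) as.integer(m$n_inv), integer(1)),
    parent = vapply(members, `[[`, character(1), "parent"),
    event = vapply(members, `[[`, character(1), "event"),
    circle = lapply(members, `[[`, "circle")
  )
  list(members = tbl, truncated = truncated)
}

#' Products of single recombination events on the master circle
#'
#' Applies every qualifying repeat pair once to the master circle: each
#' direct pair undergoes one fission (two subgenomic circles), each inverted
#' pair one inversion (one isometric master isomer). Products are
#' deduplicated by canonical form. For the published soybean repeat
#' annotation this yields 10 subgenomic circles and 8 isomers.
#'
#' @inheritParams enumerate_pairs
#' @return A `structure_pool`; see [tidy.structure_pool()] and
#'   [glance.structure_pool()].
#' @examples
#' glance(single_event_products(soybean_mt_repeats(), soybean_mt_genome(),
#'                              soybean_mt_segments()))
#' @export
single_event_products <- function(x, genome, catalog = NULL, min_shared = 500) {
  pool_closure(x, genome, catalog, min_shared = min_shared, max_events = 1)
}

#' Close the molecular pool over recombination events
#'
#' Breadth-first application of fission (direct pairs) and inversion
#' (inverted pairs) to every circle reachable from the master, including
#' events mediated by recombinant (hybrid) repeat copies created by earlier
#' events, until no new canonical structure appears. The resulting pool is
#' the set of distinct circular molecules the repeat system can generate;
#' members with size equal to the master are its isometric isomers, members
#' strictly smaller are the subgenomic ("small") circles.
#'
#' @inheritParams enumerate_pairs
#' @param max_events Maximum event depth (default unlimited).
#' @param max_circles Guard on pool size; if reached the pool is flagged
#'   truncated. Inversion-bearing closures on rich repeat systems generally
#'   do not reach a fixpoint (every inversion re-arranges anchors and
#'   enables new events), so bounded enumeration semantics are provided:
#'   see `inversion_scope`, `hybrid_pairs` and `max_inversions`.
#' @param inversion_scope Where inversion events may occur: on any circle
#'   (`"everywhere"`), only on master-sized circles (`"master_only"`), or
#'   not at all (`"never"`: pure fission cascades).
#' @param hybrid_pairs May recombinant junction copies whose content does
#'   not equal any annotated copy mediate further events?
#' @param max_inversions Maximum number of inversion events along any
#'   derivation path. `max_inversions = 1` with
#'   `inversion_scope = "master_only"` is the reading in which each
#'   isometric master isomer (one inversion each) generates subgenomic
#'   circles through fission cascades.
#' @return A `structure_pool`.
#' @export
pool_closure <- function(x, genome = NULL, catalog = NULL, min_shared = 500,
                         max_events = Inf, max_circles = 100000,
                         inversion_scope = c("everywhere", "master_only", "never"),
                         hybrid_pairs = TRUE, max_inversions = Inf) {
  inversion_scope <- match.arg(inversion_scope)
  mc <- if (inherits(x, "circle_structure")) x
        else master_circle(x, genome, catalog)
  models <- attr(mc, "models")
  res <- pool_engine(mc, models, min_shared, max_events, max_circles,
                     inversion_scope = inversion_scope,
                     hybrid_pairs = hybrid_pairs,
                     max_inversions = max_inversions)
  new_structure_pool(res$members, genome_length = mc$size,
                     truncated = res$truncated,
                     params = list(min_shared = min_shared,
                                   max_events = max_events,
                                   inversion_scope = inversion_scope,
                                   hybrid_pairs = hybrid_pairs,
                                   max_inversions = max_inversions))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a structure pool
#'
#' One row per distinct circle: canonical key, size in bp, number of master
#' blocks, event depth at first discovery, and the event/parent provenance.
#'
#' @param x A `structure_pool`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.structure_pool <- function(x, ...) {
  dplyr::select(x$members, -"circle")
}

#' Summarise a structure pool
#'
#' @param x A `structure_pool`.
#' @param ... Unused.
#' @return A one-row tibble with `n_circles`, `n_small_circles` (distinct
#'   circles strictly smaller than the master), `n_isomers` (master-sized
#'   circles other than the master itself), `max_depth` and `truncated`.
#' @export
glance.structure_pool <- function(x, ...) {
  G <- x$genome_length
  tibble::tibble(
    n_circles = nrow(x$members),
    n_small_circles = sum(x$members$size < G),
    n_isomers = sum(x$members$size == G) - 1L,
    max_depth = max(x$members$depth),
    truncated = x$truncated
  )
}

#' Histogram of circle sizes in a pool
#'
#' @param object A `structure_pool`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_pool <- function(object, bins = 30, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size / 1e3)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "grey20") +
    ggplot2::labs(x = "circle size (kb)", y = "distinct circles",
                  title = "Molecular pool size distribution") +
    ggplot2::theme_minimal()
}

#' Gene content and dispersion across pool circles
#'
#' Given gene intervals on the master, reports which circles of the pool
#' carry each gene intact (the gene's master interval fully inside one
#' un-recombined block) and summarises how each functional class of genes
#' disperses across the subgenomic circles.
#'
#' @param pool A `structure_pool`.
#' @param genes A data frame with columns `gene`, `start`, `end` and
#'   optionally `class`.
#' @return A list with `content` (circle x gene presence, long format) and
#'   `dispersion` (per class: number of subgenomic circles carrying at least
#'   one member, and whether any single subcircle carries all members).
#' @export
pool_gene_dispersion <- function(pool, genes) {
  stopifnot(all(c("gene", "start", "end") %in% names(genes)))
  genes <- tibble::as_tibble(genes)
  if (!"class" %in% names(genes)) genes$class <- "all"
  G <- pool$genome_length
  carries <- function(circ, s, e) {
    blk <- circ$blocks
    any(blk[, 1] <= s & blk[, 2] >= e)
  }
  content <- purrr::map(seq_len(nrow(pool$members)), function(i) {
    circ <- pool$members$circle[[i]]
    tibble::tibble(
      key = pool$members$key[i], size = pool$members$size[i],
      gene = genes$gene, class = genes$class,
      present = purrr::map2_lgl(genes$start, genes$end,
                                function(s, e) carries(circ, s, e))
    )
  }) |> purrr::list_rbind()
  sub <- dplyr::filter(content, .data$size < G, .data$present)
  dispersion <- sub |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_genes = dplyr::n_distinct(genes$gene[genes$class == .data$class[1]]),
      n_subcircles_with_member = dplyr::n_distinct(.data$key),
      any_subcircle_with_all = any(
        table(.data$key) >= dplyr::n_distinct(genes$gene[genes$class == .data$class[1]])
      ),
      .groups = "drop"
    )
  list(content = content, dispersion = dispersion)
}
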