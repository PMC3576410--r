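---
title: "Multipartite structure of plant mitochondrial genomes from repeat-mediated recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipartite structure of plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpool)
```

## The model

Plant mitochondrial genomes are conventionally assembled as a single
circular *master circle*, but the molecule population in vivo is
multipartite: pairs of large (> 1 kb), nearly identical repeat copies
mediate reversible homologous recombination that reorganises the circle.
The combinatorics are simple and exact:

* a **direct pair** (two homologous copies on the same strand) mediates
  *fission*: one crossover splits the circle into two subgenomic circles
  whose sizes sum exactly to the parent's;
* an **inverted pair** (opposite strands) mediates *inversion*: the arc
  between the two copies is reversed in place, producing an *isometric
  master isomer* of identical size.

`mtpool` implements these events on an exact coordinate representation —
every circle is an ordered list of signed intervals of the master genome —
and closes over them to enumerate the reachable *molecular pool*. The
soybean mitochondrial genome (402,558 bp, 45.0% GC) is shipped as the
worked example: its four large-repeat families total 59,273 bp (14.7% of
the genome) and form 13 repeat pairs, the richest repeat system reported
in a seed-plant mitochondrion.

### Coordinates

All coordinates are 1-based and inclusive on the circle; an interval with
`end < start` wraps the origin, with length `G - start + 1 + end`. This is
the only convention under which every printed copy length in the shipped
soybean annotation equals `end - start + 1`, and it is asserted row by row
in the tests.

### The segment model of nested repeat families

Copies of a repeat family need not align full-length. The soybean R1
family has five copies derived from an 8,814-bp progenitor (R1e) by
successive eliminations of terminal blocks; aligning all copies partitions
the progenitor into maximal shared segments S1–S7, with one *variant*
block: R1b and R1c carry a 673-bp block (S6\*) occupying S6's slot but
non-homologous to it. A copy is therefore a contiguous run of slots, each
slot holding either the reference segment or a variant. Two copies share
homologous content slot-wise where their content ids agree — S6\* pairs
with S6\* but never with S6. This model drives pair enumeration, anchor
placement, and the recombination engine.

`segment_family()` recovers such partitions from sequence by projecting
every copy's aligned span onto the reference copy and cutting at the union
of projected breakpoints; blocks shorter than `min_segment` (default
30 bp, chosen so the smallest genuine soybean segment of 56 bp survives)
are merged into their neighbours. Copy tails that fail to align to the
reference but align to each other are reported as variant blocks. Segment
boundaries that no copy end ever touches are unobservable and remain
merged (in the soybean system the S6/S7 boundary is of this kind).

### Solving segment lengths from printed copy lengths

Each copy's length is the sum of its member segments, a linear system over
the segment lengths. `solve_segment_lengths()` solves it by SVD, reports
uniquely determined segments, and reports minimal contiguous runs whose
*sums* are determined where individual values are not. For soybean R1 with
S6\* = 673 the system determines S3+S4 = 1,597, S4+S5 = 2,817,
S1+S2 = 4,905, leaving S1 and S2 individually free.

The shipped catalogue resolves the remaining freedom from the published
extreme segment lengths, 56 bp and 3,922 bp: since S2+S3 = 3,978 = 3,922 +
56 and S3 + S4 = 1,597 rules out S3 = 3,922, necessarily S3 = 56 and
S2 = 3,922, which forces S1 = 983, S4 = 1,541, S5 = 1,276 and
S6+S7 = 1,036. The S6/S7 split is immaterial — no recombination anchor
ever falls at their boundary — and the catalogue records an even split,
flagged as such. This resolution is validated by the fission product
sizes it implies (below), which match the published values exactly.

### Anchors and events

A pair's crossover anchor is the start of the leftmost shared segment
within each copy, mapped to the master: for ungapped, near-identical
homology every crossover position inside the shared block yields the same
product sizes, so a single canonical anchor suffices. With the resolved
catalogue, table-driven fission of the soybean master across R1b–R1d
yields circles of 79,933 and 322,625 bp, and refission of the larger
product across the R1d remnant and R1e yields 98,721 and 223,904 bp —
both exactly as published.

Each product carries *recombinant (hybrid) copies* at its junctions: the
slots of one parent up to the anchor joined with the other parent's slots
from the anchor on. Hybrids are required for multi-event cascades (the
soybean three-route example above is mediated by a hybrid), and their
homology to other copies is recomputed from slot content.

### Canonical deduplication

Circles are deduplicated by a canonical key: blocks that continue the same
master run in the same direction are merged (so the key is independent of
event history), and the key is the lexicographically minimal serialization
over all rotations of the block list and of its strand-flipped reversal.
Inverting twice across the same pair therefore returns the original key,
and the engine's products have been checked block-for-block against an
independent string-surgery oracle that performs the same events by literal
cutting, reversal and complementation of nucleotide strings.

### Enumeration semantics of the pool

Closing fission *and* inversion over the full reachable set does not
terminate in practice on a repeat system this rich: every inversion
rearranges anchor order and enables new cut placements, and the canonical
set keeps growing (hundreds of thousands of distinct circles within a few
event rounds, with no fixpoint in sight under any inversion-bearing
variant we measured). The pool is therefore enumerated under explicit,
reported semantics (`inversion_scope`, `max_inversions`, `hybrid_pairs`,
`max_events`), and `run_full_analysis(semantics_grid = TRUE)` prints the
small-circle count under each reading. The package default —
`inversion_scope = "master_only"`, `max_inversions = 1`, free fission
cascades — formalises the narrative that each isometric master isomer
generates subgenomic circles; it reaches a fixpoint (88 distinct
sub-master circles for soybean, in under a second) and is the headline
count the report and the acceptance script print. Bounded-depth variants
of the wider readings are provided for exploration; none of the readings
we consider defensible reproduces the previously reported pool size of
760 small circles, whose enumeration semantics were not specified.

## Repeat discovery

`find_large_repeats()` is a seed-and-extend self-comparison tuned for the
organelle regime (kilobase repeats at ≥ 99% identity, substitution-level
divergence): exact 21-mer seeds, chained along diagonals (forward) or
anti-diagonals (reverse) with gaps up to 200 bp, extended ungapped.
The circle is handled by indexing the single genome and extending on a
doubled linearization, so origin-spanning copies are found; detection is
rotation-invariant up to coordinate rotation, which is property-tested.
Copies are clustered from hit intervals by reciprocal overlap, and
families are single-linkage components over pairwise hits — necessary
because nested families like R1 are only partially pairwise homologous.
Recovered endpoints may extend a few bases beyond a planted repeat when
flanking bases coincide by chance (they are then genuinely repeated), so
truth-table comparisons use a ±3 bp tolerance.

`find_short_repeats()` reports the sub-kilobase band (default 50–999 bp)
plus genome coverage. The published analysis did not state its
short-repeat length floor or identity threshold, so the published coverage
figures (4.2% short-repeat coverage, 19.0% total) cannot be pinned and are
not asserted; the floor is configurable. `find_tandem_repeats()` is a
periodicity scan: for each unit length, maximal runs of positions equal to
the position one unit ahead, reported at the smallest explaining unit with
span ≥ 24 bp by default.

## Composition ledger and positional uniformity

`build_ledger()` accounts every genome position to one category. Overlaps
are resolved by an explicit priority order (coding categories — exon,
intron, rRNA, tRNA — before provenance categories), because the published
composition table does not state its overlap resolution and its rows in
fact oversum the genome; conservation (categories plus residual equal the
genome length) then holds by construction. The residual category is
configurable so that an explicitly annotated "unknown" track can be
reproduced without folding the unaccounted remainder into it.

`ks_uniformity()` tests positional uniformity. On a circle the
Kolmogorov–Smirnov statistic is not rotation-invariant, so circular mode
uses the Kuiper statistic \(V = D^+ + D^-\) with the standard asymptotic
tail series; rotation invariance of both statistic and p-value is tested.
Linear mode delegates to `stats::ks.test()`. Type-I error at
\(\alpha = 0.05\) is calibrated by simulation (500 uniform draws of
n = 200) in the test suite.

## The synthetic genome generator

`simulate_genome()` emits circular genomes with planted structure and a
truth table in the same dialect the analysis consumes: i.i.d. background
at configurable GC (default 45%, the soybean value), repeat families as
slot-runs of a generated progenitor (direct and inverted orientations,
configurable per-copy substitution divergence up to 20%, variant slots
built from unrelated sequence — the S6/S6\* device), uniformly placed
short repeats (the null hypothesis the uniformity test checks), tandem
arrays, and annotation tracks. Placement is rejection-sampled so planted
features never overlap; an infeasible packing fails before emission.
Everything is deterministic given one seed. `expected_pool()` computes
pair and single-event product counts analytically from the configuration,
independently of the detection and recombination code, so the pipeline can
be checked end-to-end: at divergence 0 detection recovers planted
coordinates (±3 bp as above) and the analysed counts equal the truth
table's.

What the generator does **not** emulate: real organelle base composition
structure (it is i.i.d.), indel divergence (substitutions only, so
detection and segmentation operate on single diagonals), gene content, or
recombination intermediates. Passing the synthetic round-trips therefore
demonstrates correctness of the combinatorial machinery under the stated
repeat model, not detection power on arbitrary real genomes.

`soybean_like_config()` mirrors the soybean topology (one five-copy
nested family with seven segments and a variant slot, one direct and two
inverted two-copy families) on a 100-kb circle — large enough that
detection, segmentation and recombination are all exercised, small enough
that the whole suite runs in about two minutes.

## Numerical and design choices

* `min_shared` defaults to 500 bp: every soybean pair shares at least
  1,541 bp, so the default excludes none of them, while sub-500-bp
  homology is below the large-repeat recombination regime.
* Variant-block detection in `segment_family()` requires tails of at
  least `min_segment` bp aligning to each other at ≥ 90% identity while
  failing the reference at the same slot; the published account gives no
  threshold, only that the variant "is different".
* Degenerate events (coinciding anchors) are skipped rather than emitting
  empty circles; a fission product always has positive size.
* The closure guards with `max_circles` (default 100,000) and flags
  truncation instead of failing.
* The engine assumes planted/annotated copies do not overlap each other on
  the circle; a non-participant copy strictly containing a cut is reported
  destroyed on the products.

## Known limitations

* Sequence-based operations assume substitution-only divergence; gapped
  homology would require an alignment-backed coordinate map at the anchor.
* The full inversion-bearing closure is enumerable only under bounded
  semantics (above); the package reports counts per reading rather than
  one unconditional pool size.
* Strand assignment within a detected family is determined only up to a
  global flip (homology fixes relative, not absolute, orientation).
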