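---
title: "loopkit: data model and methods for chromatin interaction analysis"
author: "loopkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{loopkit: data model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(loopkit))
```

# The data model

Chromosome conformation assays (Hi-C, ChIA-PET, and relatives) all reduce,
after upstream processing, to the same conceptual structure: a list of
pairs of genomic regions — *anchors* — with per-pair data such as the
number of supporting paired-end tags (PETs), a p-value and a false
discovery rate assigned by the upstream caller. loopkit encapsulates this
as the S4 class `InteractionPairs`: two parallel `GRanges` anchor vectors,
a required integer `counts` column (all values at least 1), and arbitrary
further metadata columns carried opaquely through every operation. Anchor
annotation added later lives on the anchor ranges themselves, so it
travels with subsetting and export.

Two auxiliary classes complete the model. `TagPairs` holds raw paired-end
tags — two read intervals with definite strands — and is the unit of
preprocessing. `FeatureSet` is a named class of intervals (for example
`"promoter"`) with one identifier per interval (for example a gene ID).

## Coordinate and distance conventions

All internal coordinates are 1-based and fully closed, the GenomicRanges
convention; bedpe, BED, and bedGraph input/output converts to and from the
0-based half-open disk convention at the boundary. HOMER interaction
tables are treated as 1-based closed (HOMER's post-pipeline convention is
not formally documented; the choice is declared here and applies
uniformly). The ChIA-PET-tool dialect is likewise read as 1-based closed
with a `zero_based` escape hatch.

The distance between two anchors is not uniquely defined, so three
conventions are exposed (`calculate_distances`):

* **midpoint** (default): `|mid1 - mid2|`, `mid = floor((start+end)/2)`;
* **inner**: the gap between the closest inner edges, floored at 0 for
  touching or overlapping anchors;
* **outer**: the full span, `max(end) - min(start) + 1`.

All three are symmetric in the anchor sides; trans pairs yield `NA`, never
0. Tag-pair distances use the midpoint convention: it is symmetric, robust
to read-length differences, and insensitive to whether ends were recorded
5'-to-5'.

Anchor strand is ignored by overlap and distance computations: an
interaction is an unstranded object. Strand matters only for `TagPairs`,
where it carries the self-ligation signal.

Anchor one is *not* required to precede anchor two genomically; no
ordering is enforced on input. Writers instead sort pairs by
(chrom1, start1, end1, chrom2, start2, end2), chromosomes compared
lexicographically, so all file output is deterministic.

# Self-ligation thresholds

A ChIA-PET fragment that ligates to itself produces a short-range tag pair
with a characteristic strand configuration, while true inter-ligation
pairs have independent, balanced strands. The package separates the two
populations by distance, using the strand imbalance as the signal.

`bin_strand_ratios()` bins cis tag pairs by midpoint distance into
half-open bins of `bin_width` (default 500 bp) tiling `[0, max_distance)`
(default 50 kb), and per bin counts same- and opposite-strand pairs and an
exact binomial p-value of the same-strand count against the balanced 50:50
expectation (two-sided by default; a one-sided alternative is available
since the artefact direction is known, but two-sided is the safer
default when the library protocol is unknown). Empty bins carry
`p_value = 1` and an undefined ratio.

`self_ligation_threshold_binomial()` scans bins by increasing distance and
reports as threshold the left edge of the first bin that does **not**
reject 50:50 at level `alpha` (default 0.05) and is confirmed by
`k_consecutive` (default 2) further non-rejecting bins. The confirmation
rule makes the scan robust to single noisy bins; reporting the left edge
is conservative (it classifies the whole first balanced bin as
inter-ligation-safe). If no confirmed run exists the estimator reports "no
threshold found" rather than guessing. No multiple-testing correction is
applied across bins by default — each bin is a local decision in a
sequential scan — but `adjust = "BH"` rescans on Benjamini-Hochberg
adjusted p-values, which makes the scan strictly more permissive and is
useful when many sparsely populated bins cause spurious rejections.

`self_ligation_threshold_strand_composition()` implements the
complementary long-range-reference idea: pairs spanning at least
`baseline_min_distance` (default 100 kb, at least 100 pairs required)
cannot be self-ligations, so their strand composition estimates the
assay's intrinsic baseline; the threshold is the left edge of the first
bin (plus confirmations) whose composition is statistically compatible
with that baseline. Because the baseline fraction is itself an estimate,
the default compatibility test is Fisher's exact two-proportion test of
the bin's counts against the long-range reference counts, which accounts
for sampling noise on both sides; an exact binomial test against the
point estimate of the baseline fraction is available as
`baseline_test = "binomial"`, and is slightly anticonservative when
long-range pairs are few (with ~600 reference pairs, a baseline
mis-estimate of two standard errors makes genuinely balanced bins appear
incompatible and delays the scan).

Both estimators share a monotonicity property that the test suite checks:
adding balanced long-distance pairs never increases the estimated
threshold.

## Merging tags into interactions

`merge_pairs_to_interactions()` assigns each tag end to the anchor
containing its midpoint (anchors must be disjoint, so the assignment is
unique; a read spanning an anchor boundary belongs to the anchor holding
its midpoint). Pairs with both ends assigned to two distinct anchors
contribute one supporting count to that unordered anchor pair; pairs with
an unassigned end, and self-pairs with both ends in the same anchor
(intra-anchor ligations, not interactions), are tallied separately and
reported, so that counts are conserved:
`sum(counts) == n_input - n_unassigned - n_self`.

# Annotation and interaction types

`annotate_anchors()` takes an *ordered* list of feature sets — the order
expresses importance, e.g. promoter before enhancer before CTCF — and
gives every anchor (i) the identifiers of **all** features it overlaps,
per set, and (ii) a single node class: the first set in priority order
with at least one overlap, or `"distal"` if none. Overlap means at least
one shared base; a minimum-overlap-fraction option is deliberately absent
in this version (anchor and feature sizes vary over orders of magnitude
across assays, and a single fraction default would be arbitrary).

Keeping all overlapping identifiers, not just a single winner, is a
considered choice: where several promoters or enhancers lie close
together, the data genuinely cannot resolve which one the interaction
involved, and discarding candidates would fabricate certainty. The
consequence is that identifier lists are sets (no duplicates), and
per-feature summaries may count the same pair for several features.

Interaction types are canonical labels of the unordered class pair,
joined in priority order with `"distal"` always last — `promoter:enhancer`
never appears as `enhancer:promoter`. The labels partition the set: every
pair gets exactly one label. `is_type(x, a, b)` and the shorthands
(`is_pp`, `is_pe`, `is_pd`, `is_dd`, `is_pt`) test membership
symmetrically.

`promoters_from_tss()` builds promoter windows as ±`flank` around a TSS
table (default 2.5 kb, the common convention for CAGE-derived TSS sets),
clipped at position 1.

# Summaries

`summarize_dataset()` reports pair counts, cis/trans percentages (kept at
full precision; rounding is presentation-only), interaction-type counts,
quantiles (min, 25%, median, 75%, max) of cis midpoint distances, and the
supporting-count histogram. An empty set yields zeros and empty tables
rather than errors.

`summarize_by_features()` accumulates **anchor-wise**: the counts of a
pair are added once per anchor overlapping the feature, so a pair with
both anchors in the same gene's promoter region contributes twice. This
is the literal reading of "sum of the PET counts of all anchors
overlapping the promoter region"; the alternative (once per pair) gives
systematically smaller totals, which is why the convention is stated
prominently and pinned by tests. Per partner class the table reports
summed counts and the number of *distinct* partner features.
`rank_features()` sorts stably, descending, with ties broken
lexicographically by feature identifier — deterministic top-N tables.

`viewpoint()` emulates a 4C experiment: pairs touching the viewpoint
region deposit their counts at the position of the other anchor into bins
tiling a window. Two deposition modes: `"overlap"` (default) writes the
full count into every bin the partner anchor overlaps — a coverage-style
display; `"midpoint"` deposits once into the bin containing the partner
midpoint, so total signal equals total selected counts and conservation
can be asserted exactly (the mode the tests use). When both anchors
overlap the viewpoint, both act as partners.

# Plots and export

Every figure is backed by a data table (`summary_plot_data()`,
`arc_plot_data()`) and rendering adds no computation — tests target the
tables, and the SVG outputs are self-describing (the summary figure
embeds its tables as a text comment; arc diagrams are written as
structured SVG with one `path` element per interaction). Arc height is
the supporting count or `-log10(FDR)`; an FDR of exactly 0 is drawn at
the maximum finite height in the window plus one unit and flagged, to
keep axes finite. Trans pairs have no second coordinate on the window
axis and are drawn as vertical stubs. Heights are linear in the driving
value by default (`log_height` switches to log10), and the distance
histogram uses log10-spaced bins because interaction distances span
orders of magnitude.

bed12 export represents each cis pair as one line with two blocks (the
anchors, in genomic order). Trans pairs cannot be drawn on one line and
pairs with overlapping anchors would violate the format's
non-overlapping-blocks rule; both are skipped and counted in a single
warning. Scores clamp to [0, 1000] per the BED specification; the raw
count survives in the name field. Graph export deduplicates anchors into
nodes (coordinate strings, or feature identifiers after annotation) and
merges parallel edges by summing counts.

# The synthetic data generator

All tests and the acceptance script run on seeded synthetic data
(`fixture_config()` and the `generate_*` functions); the same
configuration is always byte-identical, and generators restore the
caller's RNG state. The generator emulates, qualitatively, the structure
that matters to each method:

* tag pairs are a mixture of self-ligations (distance uniform below the
  planted cutoff `d0`, opposite strands with probability 0.95 — skewed
  but not degenerate, so the binomial scan sees realistic noise) and
  inter-ligations (truncated Pareto distances, `x_m` 1 kb, shape 0.65,
  heavy-tailed like real ligation libraries; strand combinations
  uniform);
* supporting counts are shifted geometric (support ≥ 1, long-tailed);
* p-values mix a "called" fraction (default 30%, near zero) with uniform
  null values, and FDRs are their Benjamini-Hochberg adjustment,
  emulating upstream caller output so that significance filters have
  non-trivial survivors;
* feature sets (promoter/enhancer/CTCF by default) can inject
  cross-class overlaps to exercise priority rules, and a planted
  promoter "hub" with extra enhancer contacts provides a recoverable
  ground truth for the ranking pipeline.

Default study conditions: a 4 Mb three-chromosome genome, 20,000 tag
pairs, 50% self-ligation fraction, `d0` = 5 kb, 500 bp bins — small
enough to run everywhere, large enough that both threshold estimators
recover `d0` within one bin width in the vast majority of seeded
replicates. What the generator does **not** emulate: TAD structure,
distance-dependent contact decay within domains, chromatin-state-specific
contact preferences, mappability artefacts, or sequence-level read
simulation. Passing tests therefore demonstrate correctness of the
computations, not biological realism of any particular dataset.

# Numerical and degenerate-input choices

* Exact binomial p-values come from `stats::binom.test`; the test suite
  pins them against direct pmf tail summation to relative error below
  1e-10.
* Bins tile `[0, max_distance)` half-open; a pair exactly at
  `max_distance` is excluded.
* Sorting uses radix order throughout, so ties preserve input order
  (stable) and output files are byte-stable across runs and platforms.
* Duplicate removal canonicalises end order first, so a pair and its
  mirror image collapse; the first occurrence is retained.
* bedpe scores that are not positive integers (`"."` is common in the
  wild) become counts of 1 with a warning, overridable via
  `counts_column`.
* Parse errors always carry the 1-based line number of the offending
  line.
* Empty inputs: empty files give empty objects; empty interaction sets
  summarise to zeros; an empty bin table or an all-skewed scan gives "no
  threshold found" rather than an arbitrary number.

# Problem sizes used by the checks

The shipped test suite exercises: 200 random 20-pair sets for bedpe
round trips; 1000 random bins for binomial exactness; 20 replicates of
20,000 tag pairs for threshold recovery; 50 seeds of 500 interactions
against 47 features for annotation; 20 seeds of 200 pairs for feature
summaries; 100 fixtures of 100 pairs for viewpoint conservation; and a
full two-run byte comparison of the CLI surface. These sizes were chosen
as the smallest that make the stochastic recovery statements (e.g. 18 of
20 replicates) meaningful.

# Limitations

* No genome-assembly awareness: coordinates are not validated against
  chromosome sizes, and no liftover is provided.
* Hi-C matrix normalisation, significance calling, and restriction
  fragment assignment are upstream concerns (HOMER, ChIA-PET tool,
  cooler); loopkit consumes their output and recomputes none of their
  statistics.
* Graph export writes edge lists; network analysis beyond that is left
  to igraph.
* bed12 cannot represent trans interactions; use bedpe or the edge list
  for those.
* The strand-composition threshold estimator requires a long-range
  population (≥100 pairs beyond the baseline distance) and will refuse,
  rather than extrapolate, when it is absent.
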