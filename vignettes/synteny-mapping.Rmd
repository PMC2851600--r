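---
title: "Synteny mapping between a diploid genetic map and a duplicated genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny mapping between a diploid genetic map and a duplicated genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmapr)
```

## The problem

A diploid legume with a good genetic map (linkage groups, positions in
centimorgans) can serve as a reference for a paleopolyploid relative whose
genome has been sequenced but whose duplication history obscures its
structure. After one whole-genome duplication (WGD), each mapped locus of the
diploid is expected to hit **two** places in the duplicated genome; chains of
such one-to-two anchors delineate syntenic blocks that link a linkage-group
interval (cM) to two subject-chromosome intervals (bp). Those duplicate
blocks can then be used in the other direction: an unmapped sequence whose
two best hits fall inside a known duplicate block pair can be assigned a
genetic bin *electronically*, without any wet-lab mapping.

`synmapr` implements that whole chain of reasoning as composable functions,
and ships a simulator that generates genomes with a *known* WGD +
fractionation + rearrangement history so that every stage can be validated
against ground truth.

## Pipeline and model

1. **Hit reduction** (`parse_hits`, `filter_hits`, `assign_best_two`).
   BLAST tabular hits are filtered at E-value strictly below `1e-10` and
   alignment length of at least 150 nt — the ortholog screen. Per query,
   same-chromosome hits separated by 50 nt or less are merged into one
   segment (two loci only count as distinct when the gap between them is
   *greater than* 50 nt), segments are ranked by bit score (ties: lower
   E-value, then chromosome, then leftmost position), and the top two become
   the primary/secondary locus — the one-to-two assignment. Whether nearby
   hits should be merged before choosing the best two is a genuine design
   choice; we apply the same 50-nt distinctness rule used for electronic
   mapping, uniformly, and record it in the output attributes.

2. **Block chaining** (`detect_blocks`). Anchors (mapped marker x one of its
   subject loci; primary and secondary contribute independently) are sorted
   by cM within each (linkage group, subject chromosome) pair and chained
   while consecutive gaps stay within `max_gap_cM = 15` and
   `max_gap_bp = 5e6`. A chain is a block when it has at least 3 anchors
   spanning at least 4 cM (both inclusive). No published join rule exists
   for this kind of map-to-sequence comparison at ~300-marker density, so the
   gap defaults were chosen once to chain plausibly at that scale (a ~1200 cM
   map against a ~1 Gb genome); both are arguments and are recorded in the
   `params` attribute of the result. Orientation changes do *not* break a
   chain — locally inverted loci are a real feature of such maps — and
   orientation (`direct`/`inverted`/`mixed`) is descriptive, from the match
   of bp rank order to cM rank order.

3. **Coverage statistics** (`block_stats`). Genetic coverage is the union of
   per-linkage-group cM intervals (duplicate blocks over the same interval
   count once); physical coverage is the union of bp intervals (via
   `IRanges`); euchromatic coverage removes pericentromere intervals from
   numerator and denominator.

4. **Ratios** (`neighbor_ratios`, `ratio_summary`, `duplicate_ratio_diffs`).
   The local physical-to-genetic ratio (bp in the subject genome per cM in
   the query map) is computed for consecutive anchor pairs *within* blocks
   only — cross-block pairs would span rearrangement breakpoints and mean
   nothing. Cosegregating pairs (0 cM apart) are skipped and counted.
   Duplicate blocks are paired when their cM intervals on one linkage group
   overlap by at least 50% of the shorter interval (the pairing needs a rule;
   this is ours), and compared by block-level ratio (bp span / cM span).

5. **Electronic mapping** (`electronic_map`, `interpolate_position`).
   A sequence is electronically mappable when it has two distinct-segment
   hits, both with E below `1e-30` and alignments of at least 150 nt. It is
   *placed* when at least one hit falls inside a block's (possibly extended)
   subject interval; the linkage group and bin come from that block. When the
   two hits point to different map positions, the lower-E hit wins and the
   locus is flagged, never silently dropped. The point estimate is a linear
   interpolation of cM between the bp-flanking anchors (clamped to the
   terminal anchor beyond the anchor range) — binning alone is what
   validation uses, but a point estimate is strictly more informative.

6. **Block extension** (`extend_block`). For a duplicate pair, we walk
   outward from the anchored boundaries over electronically mappable loci
   shared by the two subject regions and extend both intervals while the
   loci keep the same relative order in both regions. A single out-of-order
   locus breaks colinearity by default (`break_tolerance = 1` — the
   conservative reading of "until colinearity is broken"), and a locus
   pairing to a third chromosome stops the walk immediately. Extended
   intervals are stored beside the original anchor bounds, which are never
   modified.

7. **Duplication blocks** (`order_references`, `detect_duplicate_blocks`).
   Within the subject genome, every two-locus sequence links two regions.
   References are ordered chromosome-by-chromosome; each is annotated with
   its lowest-E duplicate on another chromosome (same-chromosome partners
   are allowed only when non-overlapping — tandem-like duplications). Maximal
   runs of at least 10 consecutive references sharing a partner chromosome
   become duplication blocks; consecutive order is enforced strictly
   (tolerance 0), since the block definition states it as a requirement.

## The simulator

`sim_config()` holds the study conditions; `simulate_synteny()` runs three
deterministic stages (each seeds its own RNG stream from `seed`, so stages
are reproducible independently):

* **Ancestor**: genes laid with exponential spacing (default 20 kb) on 10
  chromosomes of 500 genes; a central pericentromere covering 50% of each
  chromosome carries 10% of the euchromatic recombination density; cM
  positions integrate that piecewise-constant density to 100 cM per
  chromosome; 10% of genes become mapped markers. These defaults caricature
  the real comparison at desk scale: an ~1100 cM map of ~500 markers against
  a 20-chromosome duplicated genome whose pericentromeres cover roughly half
  the sequence.
* **WGD + history**: two full copies (ancestor chromosome *i* becomes derived
  chromosomes 2i−1 and 2i), each gene copy deleted independently with the
  fractionation rate (default 10%), then 20 segmental moves of geometric
  length (mean 100 genes ≈ 2 Mb), inverted with probability 0.5. Mb-scale
  segments match the modular duplicate blocks seen in real paleopolyploid
  chromosomes; segments much smaller than the marker spacing would make
  breakpoint recovery undefined rather than hard, because no junction would
  be resolvable even in principle.
* **Hits**: one hit per surviving copy. Alignment extent and offset are
  drawn per *query* (the same sequence aligns over the same stretch of both
  near-identical copies); bit score is linear in alignment length times
  (1 − divergence); E-values follow `E = N * 2^-bits` with lognormal noise,
  truncated at the 3-significant-digit precision of the tabular writer so
  emit → write → parse round-trips exactly. Optional decoy hits are drawn
  with E-values between 1e-9 and 1e-1, above the ortholog screen.

Ground truth records every event, the surviving ortholog pairs, and true
block boundaries: maximal runs of derived genes with the same ancestor
chromosome, same WGD copy, constant strand and strictly monotone ancestor
order. An excision scar (a segment removed *between* two flanks) does not
break a truth run — the flanks remain colinear, which is exactly what any
anchor-based method can observe.

### What the simulator does not emulate

No nucleotide sequences are emitted and no aligner runs; hit geometry and
E-values are drawn from parametric distributions rather than from alignment
of diverged sequence. There are no tandem arrays, no transposable-element
background producing many-to-many hits, no assembly errors, and only one
WGD. Gene density inside pericentromeres is the same as outside (real
pericentromeres are gene-poor), so the simulator's pericentromeric regions
are *harder* to get wrong than real ones. Passing the recovery suites
therefore shows the inference logic is correct at realistic densities and
noise levels — not that the thresholds are optimal for any particular pair
of real genomes.

## Validation design and numerical choices

* **Breakpoint recovery** (`block_recovery`). Matching tolerance is the
  inter-anchor gap straddling a position: marker subsampling means a
  boundary is only knowable to within one anchor gap. Precision counts only
  *breakpoint claims* — block edges whose nearest outward anchor belongs to
  a different linkage group, or chromosome-end edges. An edge where the same
  linkage group continues across a map gap asserts missing data, not a
  rearrangement. Recall is conditioned on resolvable junctions: both
  flanking true blocks carry at least 3 markers spanning at least 4 cM
  (the block definition applied to the truth), and the flanks descend from
  different linkage groups. The second condition reflects a real blind spot
  of per-linkage-group chaining: when a segment lands on its duplicate
  partner's chromosome, both copies' loci interleave in one cM-sorted chain
  and the junction is invisible at any marker density.
* **Electronic bins.** A block's bin is its anchor cM interval padded by the
  block's median adjacent-anchor cM gap on each side: terminal anchors
  censor the true block extent by about one marker spacing, and a bin should
  state the resolution honestly. The interpolated point estimate always lies
  inside the bin.
* **Extension fixed point.** Walks start at the original anchor bounds and
  the walked-out interval is unioned into the extended interval, so
  re-running extension (including over whole block sets where one block
  belongs to two duplicate pairs) is idempotent, and the extended interval
  always contains the original.
* **Ties and degenerate input.** Equal bit scores rank by lower E-value,
  then chromosome name, then leftmost start, making assignment independent
  of input row order. Cosegregating marker pairs yield no ratio but are
  counted. Blocks with fewer than two anchors interpolate to the bin
  midpoint with a `low_confidence` flag. Empty inputs give empty (or
  all-zero) outputs, not errors, except where a summary of nothing is
  meaningless (`ratio_summary`).

## Problem sizes

The bundled tests run the full default condition (10 x 500 genes, ~500
markers, 20 rearrangements) for the end-to-end suites, and 2-chromosome
genomes of 60-150 genes for unit tests and the 100-replicate extension
property. `scripts/acceptance.R` re-runs the default condition from scratch
(three simulations plus a 20-marker hold-out experiment) in well under a
minute on one core.

## Known limitations

* Chaining cannot separate interleaved duplicate copies on one chromosome
  (see above); such junctions are excluded from recall and documented here
  rather than patched over.
* Duplicate-pair formation requires 50% cM overlap; tandem-scale duplications
  and triplicated regions (not generated by a single-WGD simulator) are out
  of scope.
* The gap defaults (15 cM / 5 Mb) are scale-dependent: a map an order of
  magnitude denser or sparser warrants re-choosing them; they are plain
  arguments for that reason.
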