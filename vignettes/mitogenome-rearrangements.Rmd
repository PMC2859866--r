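---
title: "Reconstructing plant mitochondrial genome evolution from rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing plant mitochondrial genome evolution from rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorearr)
```

## The problem

Plant mitochondrial genomes (mitogenomes) evolve slowly in sequence but
rapidly in structure: within a single species, master-circle conformations
of the mitogenome can differ by dozens of inversions and carry large
duplicated fragments covering up to a third of the genome. Classical
rearrangement phylogenetics (sorting signed gene orders by inversions)
requires every marker to occur exactly once per genome, so duplicates have
historically blocked structure-based phylogenies at the species level.

`mitorearr` implements a complete pipeline around a tandem-duplication
model for those duplicates: a duplicated segment arises in tandem next to
its template, after which individual anchors of either copy may be lost
(*tandem duplication with partial loss*, TDPL) and later inversions may
separate the copies. Under this model duplicates can be collapsed or
disambiguated into `a`/`b` paralog labels, the genome becomes an ordinary
signed permutation of synteny anchors, and the standard
Hannenhalli–Pevzner machinery applies.

The stages, each exposed as ordinary functions:

1. **Duplication scan** (`find_duplicated_segments`, `duplication_stats`,
   `mask_one_copy`): seed-and-extend self-comparison of each genome on
   both strands under +1/−3 scoring, E-values from Karlin–Altschul
   statistics, statistics per genome, and masking of one copy per
   duplicate.
2. **Markers** (`extract_markers`, `reciprocal_best_hits`,
   `build_backbone`, `extract_noncoding_markers`): coding markers from
   annotations, orthology by reciprocal best hits with length-class
   E-value thresholds, plus non-coding markers from co-linear backbone
   fragments found by unique k-mer anchor chaining.
3. **GSS construction** (`group_markers_into_anchors`, `assign_numbers`,
   `build_gss_bpisac`): markers that travel together in every genome merge
   into synteny anchors; anchors are numbered along a reference genome and
   signed by strand, giving the *Genome Structure Sequence before paralog
   identification and synteny anchor collapsing* (GSS bpisac).
4. **Duplicate resolution** (`build_neighborhood_graph`,
   `detect_tandem_regions`, `collapse_tandem_region`,
   `disambiguate_paralogs`): the four-step duplicate framework described
   below.
5. **Rearrangement analysis** (`inversion_distance`, `sorting_scenario`,
   `breakpoint_distance`, `distance_matrix`): exact inversion distances
   and parsimonious scenarios on the final GSSs.
6. **Phylogeny** (`bionj_tree`, `jackknife_support`,
   `mgr_like_ancestors`, `place_duplication_events`): BIONJ trees, block
   jackknife support, greedy ancestral gene orders, and per-branch event
   scenarios with duplications reintroduced.
7. **Sequence cross-check** (`count_substitutions`, `k2p_distance`,
   `sequence_tree`): Kimura two-parameter divergence on backbone
   alignments and a bootstrapped sequence tree to compare against the
   structure tree.
8. **Simulation** (`simulate_history`, `simulate_marker_genomes`,
   `simulate_sequences`): a seeded generator of circular signed-block
   genomes evolving by inversions, TDPLs and losses, with a replayable
   event log and optional rendering into annotated nucleotide genomes.

## The inversion distance

A final GSS is a circular signed permutation. We linearize it by pinning
an origin (by default the smallest label, reverse-complementing the circle
first when the origin lies on the minus strand); any rotation or
reflection of the same circle yields the identical canonical form, and the
resulting linear distance equals the circular one.

The distance between two permutations is computed exactly from the
breakpoint graph of the relabelled permutation extended by framing
elements:

\[ d = b - c + h + f \]

with \(b\) breakpoints, \(c\) non-trivial alternating cycles, \(h\)
hurdles among unoriented components and \(f\) the fortress indicator.
Hurdles are detected as unoriented components whose positions form a
single circular run among all unoriented-component positions; a hurdle is
a superhurdle when deleting it turns another unoriented component into a
hurdle, and a fortress is an odd number of hurdles, all superhurdles.
The implementation is quadratic per pair, which is ample at the scale of
this problem (circa 70 blocks).

Correctness is not argued but measured: an independent breadth-first
search over the reversal graph (no breakpoint-graph theory) provides the
distance for every signed permutation up to \(n = 6\) exhaustively
(46,080 permutations at \(n = 6\)) and for sampled pairs at \(n = 7\);
the test suite asserts exact agreement. Sorting scenarios are built
greedily from oriented gray edges (falling back to an exhaustive scan in
hurdle configurations), always decreasing the distance by one per step,
with ties broken by the lexicographically smallest interval so scenarios
are reproducible; every scenario is replay-checked.

## The duplicate framework

Duplicates are handled in four steps:

1. **Collapse detectable tandem regions.** Labels occurring exactly twice
   group into candidate regions. The two copies are separated at a split
   point between the last first-occurrence and the first
   second-occurrence; flanking singletons in the ambiguous zone are
   assigned by neighborhood-graph affinity (the weighted graph counting,
   over all genomes, how often two anchors are separated by at most one
   anchor — duplicate occurrences each contribute, and each circular
   position pair at distance 1 or 2 is counted once). A second copy
   inverted as a whole is recognized and flipped; other internal
   rearrangements are reported via the shared-anchor sorting scenario but
   leave the region "irreconcilable" and uncollapsed. Collapsing replaces
   the two copies by their minimal common supersequence on the
   shared-anchor scaffold, reintroducing anchors lost in one copy at
   their positional slot.
2. **Disambiguate remaining paralogs.** For anchors still duplicated, the
   copy adjacent (within the neighborhood distance) to the anchor's
   strongest *unique* neighborhood partner receives suffix `a`, the other
   `b`; genomes resolved later reuse the flank profile of the first
   resolved genome.
3. **Complete single-copy genomes with virtual tandem copies.** A genome
   carrying one copy of a split anchor receives the missing suffixed label
   in tandem, downstream in the anchor's own reading direction and with
   `a` preceding `b`. Because every genome then shares the new adjacency,
   the insertion provably changes no pairwise inversion or breakpoint
   distance — a property the tests check on random instances rather than
   assume.
4. **Delete the unresolvable.** Anchors whose copies have symmetric
   neighborhoods are removed from *all* genomes, keeping the label
   alphabet common.

### What collapsing can and cannot recover

When both copies of a tandem region lost anchors independently, the true
pre-duplication order is a common supersequence of the two copies.
If the minimal common supersequence is unique, it *equals* the true order
(the truth is itself a minimal common supersequence), and collapsing is
provably exact; the package flags this case (`unique_merge`). When several
minimal supersequences exist — an anchor lost from copy A and another
lost from copy B compete for the same slot — the true interleaving is
not identifiable from the sequence alone, and the deterministic
copyA-first tie-break is applied. The acceptance checks therefore assert
exact recovery on every identifiable case (and on all loss-free cases,
which are always identifiable) and merely report the overall rate, which
at loss probabilities 0.3–0.6 settles around 60%: that number measures
the identifiability of the process, not an algorithmic deficiency.

## Trees, support, scenarios

Distance matrices feed `ape::bionj`; rooting uses a declared outgroup
(rooted at the outgroup MRCA, with a warning, when the outgroup is not a
clade). Support is estimated by a block jackknife: per replicate a random
10% of GSS blocks (virtual copies included — they are ordinary blocks of
the final GSS) is deleted from all genomes, the matrix and tree are
recomputed, and the recurrence of each full-data bipartition is recorded.
Supports are attached to unrooted bipartitions, since replicate trees may
root differently.

Ancestral gene orders use an MGR-like greedy heuristic: repeatedly apply
to some genome the single inversion that most decreases the sum of its
distances to all others (ties: smallest interval, then lexicographic),
merging genomes that become identical into ancestor nodes; when no
inversion improves the total, the closest allowed pair is merged by
sorting one genome into the other. The heuristic stops at a local
optimum — the underlying multiple-genome rearrangement problem is
NP-hard — and simulations in the test suite track how close its score
stays to the true event count.

`place_duplication_events` reintroduces duplications on the tree: a
duplication shared by a set of genomes is placed on the branch above
their most recent common ancestor (the most parsimonious position is just
before the speciation), genome-specific duplications on terminal
branches, and per-copy losses on the stems of the maximal clades lacking
that copy; non-monophyletic patterns are placed at the MRCA with a
homoplasy warning. Within a branch, `event_partial_order` frees
non-overlapping inversions to commute while ordering overlapping ones and
keeping duplications before events that touch their labels.

## Sequence-level cross-check

Backbone fragments are globally aligned per fragment and concatenated;
substitutions are counted with gap and N columns wholly excluded
(pairwise deletion). The per-10 kb substitution rate is defined as
substitutions per aligned non-gap site × 10\(^4\) — the natural reading
of a "per 10 kb" rate, and any constant cancels in the backbone/gene
rate *ratios* in which the quantity is used. The Kimura two-parameter
distance \(d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)\) is computed
from transition and transversion proportions and cross-checked in the
tests against an independent implementation (`ape::dist.dna`, model
K80). The sequence tree is BIONJ on the K2P matrix with bootstrap over
alignment columns.

## The simulator and what passing tests mean

`simulate_history` evolves the identity circle of `n_blocks` anchors
(default 69, the anchor count of the motivating dataset) along a rooted
tree, by default a random 8-leaf topology with branch lengths uniform on
[2, 6] events. Two branch models are provided:

* `"poisson"` (default): Poisson(branch length) events drawn from an
  event mix, by default 80% inversions, 10% TDPLs, 10% duplicate losses —
  mostly inversions with occasional duplications, mirroring the event
  vocabulary of the model;
* `"uniform"`: exactly `round(branch length)` inversions per branch plus
  at most one TDPL (probability 0.5) — the regime used by the tree
  recovery and congruence checks, where the per-branch inversion count is
  the controlled quantity.

Inversions act on uniform circular intervals of at most half the genome;
TDPL duplicates a segment of 1–12 anchors in tandem and deletes each
anchor of each copy independently with probability `q = 0.3`, constrained
so every anchor keeps at least one copy (in the motivating data all
anchors are common to all genomes); a loss event deletes one random
duplicated-copy anchor. Every run records a positional event log whose
replay must reproduce the leaves exactly.

`simulate_marker_genomes` renders a history into annotated nucleotide
genomes: each anchor becomes a random marker (protein-gene-like 400–1500
bp with probability 0.7, tRNA-like 60–90 bp otherwise — sizes chosen so
that near-identical markers clear the length-class E-value thresholds the
marker stage uses), mutated along the tree, with duplicate copies
identical within a genome, separated by genome-specific random spacers.
This emulates low-divergence organellar genomes with shuffled block
order. It deliberately does **not** emulate indels, recombination
intermediates (subgenomic circles), nested or 3+-copy duplications, or
conserved intergenic DNA; conclusions from passing tests extend to real
data only insofar as those features are secondary, and the marker stage's
behaviour under high divergence or heavy annotation error is untested.

Numerical and procedural choices worth knowing: alignment E-values use
ungapped Karlin–Altschul statistics (λ solved exactly; K by the
renewal-series formula, validated against published ungapped DNA
constants) and are compared in log10 space because values near the
1e-300 cutoff underflow doubles; gap penalties for the marker aligner
(open 5, extend 1 under +1/−3) are package defaults, stated because they
influence aligned-length differences; the backbone chainer treats the
minimum-island parameter as absorbed into the spacing test (a gap
discrepancy above `max_gap` splits a chain); duplicate scans double the
genome to catch origin-spanning repeats and N never matches, which makes
masking idempotent; anchors with three or more copies are out of the
TDPL model and are reported, then excluded.

## Scale of the shipped checks

The packaged tests and the acceptance script run the oracle equivalence
exhaustively to \(n = 6\) plus 1000 sampled pairs at \(n = 7\); 1000
random scenario replays at \(n\) 20–72; 500 single-TDPL round trips at
\(n = 69\); 100 simulated 8-leaf histories for tree recovery with
200-replicate jackknives; 50 joint simulations for sequence/structure
congruence; and 200 virtual-copy neutrality instances. These sizes keep
the whole suite in a few minutes while leaving the statistical
assertions comfortably powered.
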