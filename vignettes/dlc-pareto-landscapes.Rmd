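---
title: "Pareto-optimal DLC reconciliation landscapes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto-optimal DLC reconciliation landscapes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlcpareto)
```

## The problem

Gene trees disagree with species trees. Under the duplication-loss-coalescence
(DLC) model the disagreement is explained by three kinds of events: gene
**duplications** (a new locus is born on a gene branch), gene **losses** (a
locus present in a species branch leaves no sampled descendant at its bottom),
and **deep coalescences** (two or more lineages of the same locus fail to
coalesce within a species branch, a population-level effect also known as
incomplete lineage sorting). Maximum-parsimony reconciliation assigns each
event type a cost and seeks a reconciliation of minimum total cost
`d*C_D + l*C_L + c*C_C`. The costs are rarely known, and the optimal
reconciliation can change qualitatively as they vary.

This package computes, for a rooted binary gene tree, a rooted binary species
tree and a (not necessarily one-to-one or onto) leaf mapping, the **full set
of Pareto-optimal event counts** `<d, l, c>` over all reconciliations, the
number of optimal reconciliations attaining each count, and the frequency of
every constituent event among them. From those counts it partitions a
two-dimensional duplication/loss cost rectangle (coalescence cost normalized
to 1) into **equivalence regions**: maximal sets of cost points sharing the
same optimal-reconciliation set. No cost setting has to be chosen in advance;
the landscape shows every answer the parsimony criterion can give.

## The reconciliation structure

A reconciliation is represented as a labeled coalescent tree (LCT): a
**species map** assigning every gene node to a species branch, a **locus
map** assigning every gene node a locus, and a **partial order** on gene
nodes within a species branch and locus. The optimal species map is always
the LCA map, so it is fixed first; the species tree is pruned to the subtree
below the image of the gene root; *implied nodes* are then inserted so every
gene branch spans exactly one species branch. The insertion rule adds one
unary node per intermediate species on the path between the endpoint images,
plus a boundary node at the parent's species when the parent sits strictly
inside its species branch (it has another child mapping to the same
species). Without that second case a branch can cross a species boundary
with no node at the bottom of the upper branch, and the tops/bottoms
bookkeeping below would miscount entering lineages.

For each species branch `s`, `nodes(s)` are the gene nodes assigned to it,
`bottoms(s)` the subset whose children all map below `s` (or that are
leaves), and `tops(s)` the bottoms of the parent branch (the gene root for
the species root). The width `k`, the largest top or bottom set, governs the
complexity: the algorithm is exponential in `k` but polynomial in the number
of species, so `reconcile_landscape()` refuses instances with `k` above
`max_width` (default 8).

Event counting within one species branch, given its restricted locus map:

* **duplications** are the branches whose endpoints carry different loci;
  each creates a locus new to the branch;
* **losses** are the loci present at the top of the branch — over *all*
  tops, because a locus present at the bottom of the parent branch is
  inherited by both daughter species — or created inside it, that are absent
  from its bottom;
* **coalescence at speciation** counts, per locus, the lineages that
  actually *enter* the branch (tops with a child inside it) minus one.
  Entering lineages, not all tops: a lineage that continues only into the
  sibling species never existed in this branch's population and cannot fail
  to coalesce there (whereas a locus is inherited by both sides, which is
  why losses do use all tops);
* **coalescence at duplication** depends on the partial order: at each
  duplication, the number of contemporaneous open lineages on the mother
  locus minus one. A lineage is open if its start precedes the duplication
  and its end does not; the duplicating branch itself counts as open.

The partial order is represented as one total order (a linear extension of
gene-tree ancestry) per species and mother locus with at least one departing
duplication, over that locus's gene nodes plus its departing duplications.
Bottom nodes participate: an order in which a bottom precedes a duplication
models a duplication happening after that lineage's divergence, which is
exactly what makes a pair of paralogous genes in one species scorable as one
duplication and zero coalescences. Distinct order families are distinct
reconciliations; since duplications and losses do not depend on the order,
only coalescence-minimal families survive into the Pareto set, and the
reconciliation count `kappa` counts them.

## Descriptors and the dynamic program

The unit of computation is the *descriptor* `<v, kappa, E>`: an event count,
the number of reconciliations attaining it, and an event set mapping each
event identity to the number of those reconciliations containing it. Two
merge operations preserve Pareto-optimality: the union `oplus` (alternative
solutions of the same subproblem; equal counts merge by adding `kappa` and
event frequencies) and the product `otimes` (independent subproblems;
counts add, `kappa` multiplies, frequencies inflate by the partner's
`kappa`). Pareto filtering is a sort-and-sweep over `(d, l)` with a running
minimum of `c`; a Pareto set holds at most one count per `(d, l)` pair.

The dynamic program enumerates, per species branch and reachable top-locus
pattern, every *tile* — a sub-locus map given by a subset of flagged
branches, with bottom loci required distinct at extant species — and folds
each tile's orders into a single descriptor. Tiles are grouped by their
*relative locus pair*: the dense first-occurrence renumbering of the
tops-then-bottoms locus sequence, which is exactly the information a parent
or child needs. A post-order pass stitches the tables: for an internal
species, child solutions for the bottom pattern (re-indexed densely as the
child top pattern) are combined with the species' own tiles, and the union
over bottom patterns taken; the species root has a single top pattern and
yields the global front.

Event identities are label-free strings (stable pre-order node ids, never
locus numbers), so identical events merge across reconciliations with
different locus numberings. Two refinements are worth spelling out:

* **Speciation events** ("a bottom locus continues, un-duplicated, into at
  least one child species") are null events for the count but tracked for
  support. Whether a locus continues into a child is decided by the child's
  tile, after child tiles have been folded the information is gone, so the
  tables carry an extra key: the *continuation profile*, the subset of a
  branch's top loci that continue into it. The stitch combines the two
  children's profiles and emits one speciation event per continuing bottom
  locus, with exact frequency; `k <= kappa` holds by construction.
* **Merged duplication identities.** A duplication that differs from
  another only by which lineage set keeps the mother locus and which takes
  the daughter locus yields the same paralogs. The merged identity (the
  unordered pair of bottom-lineage sets) is a function of the whole
  sub-locus map, not of the plain (species, branch) identity, so tiles emit
  both identities at source; event sets feed support statistics only, never
  the counts, so this is free of side effects. `region_support(...,
  merge_dups = TRUE)` selects the merged view with exact frequencies.

## The cost landscape

With the coalescence cost as the unit, an event count `v` is optimal at
`(C_D, C_L)` iff `d*C_D + l*C_L + c` is minimal over the front. Each
region is the intersection of the cost box with the half-planes
`(d-d')C_D + (l-l')C_L <= c'-c`, a convex polygon, segment or point. All
half-plane coefficients are integers and box bounds are small rationals, so
the package clips with exact rational arithmetic (numerator/denominator
pairs, far below the 2^53 exact-integer range of doubles): region
dimensions are classified without tolerances, and zero-area regions —
cost settings that are knife-edge compromises between counts — are reported
rather than lost to floating-point noise. Regions are closed; neighbours
share boundaries. `verify_landscape()` certifies a partition exactly: the
positive-area regions' areas sum to the box area, and at random
integer-weight interior points of each region the owning count is a strict
minimizer (an exact integer sign test after clearing the common
denominator).

Support statistics: *region support* of an event is `k / kappa` within one
region's descriptor; *consensus support* is the fraction of regions whose
optimal set contains the event at all. Degenerate regions count in the
denominator.

## Validation: an independent brute force

`enumerate_all_lcts()` enumerates every reconciliation of a small instance
directly: every subset of gene branches flagged as duplications (one fresh
locus each, inheritance elsewhere, extant-species distinctness enforced),
times every combination of linear extensions, enumerated by exhaustive
permutation filtering. Events are derived straight from the definitions,
with no tiles, relative patterns or descriptor algebra; per-species results
are memoized on the branch's dense locus pattern, which changes the running
time but not a single computed value. `oracle_front()` groups by count and
drops dominated groups. The central correctness property asserted by the
test suite is exact equality — counts, reconciliation counts and event
frequencies — between the stitched front and this enumeration over an
exhaustive battery of all gene-tree shapes with up to 4 leaves, all
species-tree shapes with up to 3 leaves and all leaf maps, plus 200
generated instances with up to 5 gene leaves and 4 species. Problem sizes
were chosen so the exhaustive enumeration stays tractable while covering
every qualitative configuration (implied chains, empty branches, mixed
boundary nodes, multi-locus tops).

## The synthetic generator

`generate_instance()` draws a species tree by uniform random joins and runs
a forward gene-family simulation: per species branch each lineage is lost
with probability `loss_rate` and duplicated a Poisson(`dup_rate`) number of
times; at a speciation every surviving lineage is inherited by both
daughters; `genes_per_species` adds terminal-branch duplications. ILS-like
incongruence is induced afterwards by Poisson(`ils_rate` x internal nodes)
random NNI moves on the gene tree. With all knobs zero the instance is
congruent (width 1, one gene per species). Defaults used in the test
batteries (`dup_rate` up to 0.4, `loss_rate` up to 0.15, `ils_rate` up to
0.3) keep widths mostly in 1-3 with occasional 4, matching the regime where
gene families are moderately discordant; the generator emulates topology
only — no branch lengths, no explicit coalescent times — so passing tests
say nothing about rate estimation, only about the combinatorial
reconciliation structure.

## Numerical and degenerate-input choices

* All orderings ("canonical order") are pre-order indices of the implied
  gene tree; determinism is asserted by byte-identical repeated runs.
* Reconciliation counts are stored as doubles (they grow multiplicatively);
  event frequencies likewise. Counts `d, l, c` are integers throughout and
  compared exactly.
* A species branch with no gene nodes and no tops carries the trivial
  descriptor `<0,0,0>`, one reconciliation, no events. A branch whose tops
  carry loci that cannot continue (no lineage enters) scores losses for
  those loci.
* At a leaf species several distinct all-distinct bottom patterns can be
  realized; the leaf case of the DP takes the union over them (nothing
  below a leaf depends on the pattern).
* Duplications whose daughter locus dies immediately are enumerated and
  scored (duplication plus loss); they are never Pareto-optimal but
  correctness does not depend on pruning them.
* Cost-box bounds accept exact fraction strings (`"1/5"`); plain numerics
  are converted by continued fractions with denominators up to 1e6.

## Limitations

* The tile enumeration is exponential in the width `k`; wide, highly
  discordant families are refused (`max_width`). This mirrors the
  fixed-parameter nature of the underlying problem.
* The package reports event counts, reconciliation counts, event
  frequencies and regions; it does not reconstruct explicit optimal
  reconciliations (the brute-force enumerator does, but only at toy sizes).
* The two coalescence flavours share one cost; separate costs would add a
  dimension to the landscape.
* Consensus support weights every region equally, regardless of area — a
  deliberate choice matching the region-equivalence view, not a posterior
  over cost space.
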