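# dlcpareto

Pareto-optimal reconciliation landscapes for gene families under the
duplication-loss-coalescence (DLC) model.

## What it does, and for whom

Reconciling a gene tree with a species tree under the DLC model explains
their incongruence through gene **duplications**, gene **losses** and
**deep coalescences** (incomplete lineage sorting). Maximum-parsimony
reconciliation minimizes `d·C_D + ℓ·C_L + c·C_C` — but the event costs
`C_D, C_L, C_C` are rarely known, and the optimal reconciliation can change
with them. This package is for phylogeneticists who want the answer for
*every* cost setting at once:

* the full set of **Pareto-optimal event counts** `⟨d, ℓ, c⟩` over all
  reconciliations (labeled coalescent trees: species map, locus map,
  partial order), computed by a tile-based dynamic program over the species
  tree that is exponential only in the width `k` of the gene-tree
  decomposition (`k` = largest set of gene lineages crossing one species
  branch; congruent families have `k = 1`);
* for each count, the number `κ` of optimal reconciliations and the
  frequency of every constituent event (duplications, losses, both kinds
  of coalescence, speciations);
* the partition of the duplication/loss cost rectangle — coalescence cost
  normalized to 1, so a count is optimal at `(C_D, C_L)` iff
  `d·C_D + ℓ·C_L + c` is minimal — into **equivalence regions** computed
  with exact rational half-plane intersection, so zero-area regions
  (segments and points of cost space) are found, not lost to rounding;
* per-event **region support** (`k/κ` within a region) and **consensus
  support** (fraction of regions containing the event), with an optional
  merged identity for the two symmetric labelings of each duplication.

A brute-force enumerator of all reconciliations (`enumerate_all_lcts()`)
provides an independent check on small instances, and a seeded synthetic
instance generator (`generate_instance()`) produces test families with
tunable duplication, loss and incongruence intensity.

## Worked example

A classic incomplete-lineage-sorting pattern: gene tree `((a1,b1),b2)` on
species tree `(A,B)` with `a1 → A`, `b1, b2 → B`.

```r
library(dlcpareto)

fr <- reconcile_landscape("((a1,b1),b2);", "(A,B);",
                          c(a1 = "A", b1 = "B", b2 = "B"))
fr
#> Pareto-optimal reconciliation front (width k=2):
#>   <d=1, l=0, c=1>  kappa=2  events=5
#>   <d=1, l=1, c=0>  kappa=2  events=6
```

Two explanations survive: a duplication inside species B with one failure to
coalesce (`⟨1,0,1⟩`), or an earlier duplication in the ancestral branch with
a loss in A (`⟨1,1,0⟩`); each is realized by two reconciliations. The cost
rectangle `[1/5, 5]²` splits accordingly:

```r
box <- cost_box("1/5", 5, "1/5", 5)
regions <- compute_regions(fr, box)
for (r in regions)
  cat(sprintf("region <%s>: dim %d, area %.3f, kappa %g\n",
              paste(r$v, collapse = ","), r$dim, r$area, r$descriptor$kappa))
#> region <1,0,1>: dim 2, area 19.200, kappa 2
#> region <1,1,0>: dim 2, area 3.840, kappa 2

event_support_table(regions, fr$dec$S)
#>   region event_count    event_id                   kind species region_support consensus_support
#> 1      1       1,0,1 cspec|3|2,5 coalescence_speciation       B            1.0               0.5
#> 2      1       1,0,1     dup|3|4            duplication       B            0.5               0.5
#> 3      1       1,0,1     dup|3|6            duplication       B            0.5               0.5
#> 4      1       1,0,1  spec|1|2,5             speciation      s1            1.0               0.5
#> 5      2       1,1,0     dup|1|2            duplication      s1            0.5               0.5
#> ...
```

The two counts trade one loss against one coalescence, so the boundary is
the exact line `C_L = 1`; region areas are exact rationals and sum to the
box area (`19.2 + 3.84 = 4.8²`).
Each duplication placement has support `0.5` within its region; with
`merge_dups = TRUE` the two symmetric placements merge into one fully
supported duplication.

The same computations are available from a shell:

```sh
exec/dlcpareto landscape --gene-tree gene.nwk --species-tree species.nwk \
    --smap map.tsv --dup-range 1:5 --loss-range 1:5 --out results/
exec/dlcpareto oracle-check --gene-tree gene.nwk --species-tree species.nwk --smap map.tsv
exec/dlcpareto generate --n-species 16 --dup-rate 0.3 --seed 1 --out fixture/
```

`landscape` writes `descriptors.json`, `regions.json`, `events.tsv` and
`summary.json`.

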