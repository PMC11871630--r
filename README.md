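# panmem

Compact pangenome indexing with maximal-exact-match overlaps, for
arbitrary-length k-mer membership and conservation queries.

## The problem

Given a pangenome of *t* genomes, researchers routinely ask of a substring
from a reference genome: *which other genomes contain it?* (membership)
and *how many genomes contain it?* (conservation). k-mer and de Bruijn
indexes answer these only at the single k they were built with, and grow
with the union of all k-mers. `panmem` targets users who want **one small
index that answers for every k at once** — e.g. to explore sequence
conservation across a locus at several resolutions.

## The method

One genome of the collection is designated the **pivot** G₁; all queries
use k-mers drawn from the pivot, at pivot coordinates.

* For each other genome Gₙ, the **matching statistics**
  MS[j] = length of the longest suffix of P[1..j] occurring anywhere in Gₙ
  or its reverse complement (contigs separator-delimited) are computed
  exactly with a suffix automaton. Successive values satisfy the sawtooth
  property MS[j] − MS[j−1] ≤ 1.
* **MEMs** (maximal exact matches) are the peaks of this landscape —
  positions with MS[j] ≥ MS[j+1], or j = m — each peak of height ℓ giving
  the 0-based interval [j−ℓ, j). A pivot k-mer occurs in Gₙ iff it lies
  entirely inside a MEM, *for any k*.
* The index stores only the **overlaps of consecutive MEMs** [c, b)
  (equal start/end when MEMs adjoin): a k-mer is absent iff it spans an
  overlap with overhang on both sides — or touches a **gap record**, a
  maximal run of MS = 0 positions covered by no MEM.
* For conservation, the MS rows are **column-sorted descending** into the
  order matrix O; row i is again a sawtooth, and containment in an
  order-i MEM certifies presence in ≥ i non-pivot genomes. Reported
  counts include the pivot (values in [1, t]). Nested orders allow early
  stopping and **decile (quantile) subsampling** — keep only order rows at
  counts ⌊q·t⌋ (for t = 89: 8, 17, 26, …, 89) and floor answers onto them.
* Discarding overlaps longer than *l* losslessly restricts queries to
  k ≤ l + 2 (**interval-length filtering**).
* Records live in a ZSTD-compressed Parquet table sorted by
  (contig, start, end, label), with metadata in the footer; region reads
  push the intersection predicate into the scan.

A seeded synthetic-pangenome simulator plus brute-force presence /
conservation oracles make every stage testable without downloads.

## Worked example

```r
library(panmem)

cfg <- simulation_config(seed = 42, t = 5, pivot_length = 10000,
                         substitution_rate = 0.02)
gs  <- simulate_pangenome(cfg)              # gs[[1]] is the pivot

idx <- "cons.parquet"
build_index(gs[[1]], gs[-1], idx, mode = "conservation")
open_index(idx)
#> <panmem_index> cons.parquet
#>   mode: conservation, t = 5, pivot = g1
#>   contigs: chr1 (10000 bp)

reg  <- query_region("chr1", 2000, 2600)    # 0-based, half-open
cons <- conservation_query(idx, reg, 31)    # any k works on the same index
table(cons)
#> cons
#>   1   2   3   4   5
#>   4 140 236 115  75
```

Of the 570 31-mers starting in `chr1:2000-2600`, 75 occur in all five
genomes, 236 in exactly three (the pivot plus two mutated copies), and 4
are private to the pivot. A membership index answers per genome:

```r
build_index(gs[[1]], gs[-1], "mem.parquet", mode = "membership")
mem <- membership_query("mem.parquet", reg, 31)
rowSums(mem)   # k-mers present per genome (pivot trivially all 570)
#>  g1  g2  g3  g4  g5
#> 570 302 320 356 279

identical(as.integer(cons),
          oracle_conservation(gs[[1]], gs[-1], reg, 31))
#> [1] TRUE
```

The same pipeline is scriptable from a shell via the installed
`exec/panmem` entry point (`simulate`, `build`, `filter`, `sample`,
`query-membership`, `query-conservation`, `export-bed`, `plot`).

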