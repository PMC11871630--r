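---
title: "MEM-overlap pangenome indexing: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MEM-overlap pangenome indexing: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmem)
```

## The problem

Given a pangenome — a collection of $t$ genomes $G_1, \dots, G_t$ — two
questions recur in comparative work: *membership* (is this substring of a
reference genome also present in genome $G_n$?) and *conservation* (in how
many of the $t$ genomes does this substring occur?). k-mer databases answer
these only for the single $k$ they were built with, and their size grows
with the union of all k-mers. `panmem` instead indexes the *maximal exact
matches* (MEMs) between one designated genome — the **pivot** $G_1$ — and
every other genome. Because a k-mer drawn from the pivot is present in
$G_n$ exactly when it lies entirely inside a pivot-vs-$G_n$ MEM, a single
MEM-derived index answers queries for *every* k-mer length at once. The
price is that queries are restricted to k-mers that occur in the pivot, at
pivot coordinates.

## Matching statistics and the sawtooth

For a pivot contig $P[1..m]$ and target text $T$, the matching statistics
are
$$\mathrm{MS}[j] = \max\{\ell : P[j-\ell+1..j] \text{ occurs in } T\},$$
the length of the longest suffix of each prefix of $P$ found anywhere in
$T$. Here $T$ is the concatenation of every contig of $G_n$ *and its
reverse complement*, each terminated by a separator byte that is not a
nucleotide, so a match can never bridge two contigs or two strands.
Separator bytes are drawn from a pool of distinct punctuation bytes; even
where byte values recycle, no match can contain one, so boundaries stay
unbridgeable.

`compute_matching_statistics()` builds a suffix automaton over $T$ and
streams $P$ through it — linear construction, one amortized automaton step
per pivot character, and exact by construction. The test suite checks it
against a naive quadratic scan that re-searches every suffix with
`grepl(fixed = TRUE)`.

Consecutive values can rise by at most one ($\mathrm{MS}[j] -
\mathrm{MS}[j-1] \le 1$, the *sawtooth property*): appending a character
extends the best suffix match by at most that character. MEMs are the
**peaks** of this landscape — positions with $\mathrm{MS}[j] \ge
\mathrm{MS}[j+1]$, plus $j = m$ — each peak of height $\ell \ge 1$ mapping
to the 0-based half-open pivot interval $[j-\ell,\, j)$. The mapping is a
bijection, and `reconstruct_ms()` inverts it exactly.

## Overlap records instead of MEMs

The index does not store MEMs. For each consecutive MEM pair $[a,b)$,
$[c,d)$ it stores only their shared interval $[c,b)$ — a proper overlap
when $c < b$, or a zero-length *point record* $[c,c)$ when the MEMs
adjoin. A k-mer $[x, x+k)$ is absent from a genome iff it spans such a
record with overhang on both sides ($x < c$ and $x + k > b$): it then fits
in neither MEM of the pair, and no other MEM can contain it. Overlaps are
both smaller than MEMs and more compressible, and the spanning test is
independent of $k$ — the heart of the arbitrary-$k$ property.

**Gap records.** Positions where $\mathrm{MS} = 0$ (possible with novel
characters, N runs, or entirely missing sequence) are covered by no MEM,
and the spanning test alone cannot express that. Every maximal zero run is
therefore stored explicitly as a *gap record* (`is_gap = TRUE`); any k-mer
merely intersecting a gap is absent. With gap records the overlap route is
exactly equivalent to MEM containment, which the suite verifies by running
both routes side by side.

## Order-MEMs and conservation

Stacking the $t-1$ MS vectors row-wise and sorting every column in
descending order yields the order matrix $O$: row $i$ holds the $i$-th
largest match length at each position, with genome identity discarded.
Each row of $O$ is again a sawtooth, so MEM extraction applies row-wise.
Containment in an order-$i$ MEM certifies presence in at least $i$
non-pivot genomes, and the rows are nested: containment at order $i+1$
implies containment at order $i$. The conservation count at $x$ is
therefore $1 + \max\{i : \text{k-mer contained at order } i\}$ (the $+1$
is the pivot itself, so reported values live in $[1, t]$; subtract 1 to
compare with k-mer counters that exclude the reference).

Nesting justifies **early stopping**: `conservation_query()` examines
orders from the deepest down and stops once every position is resolved;
`early_stop = FALSE` forces the exhaustive sweep, and the two are asserted
identical on every test fixture. Within a column, tied values need no
tie-breaking — after sorting, only the multiset of lengths matters.

## Quantile (decile) sampling

Full conservation resolution is often unnecessary for large $t$. For a
quantile set $Q$ (deciles by default), `quantile_thresholds()` keeps the
conservation counts $\lfloor q\,t \rfloor,\ q \in Q$ — e.g. for $t = 89$
the deciles 8, 17, 26, …, 89 — and the index retains only the order rows
$c - 1$ for each kept count $c$, relabelled with $c$ itself: the minimum
count that row certifies. Queries then floor the exact count onto the
retained set; uncertified positions report 1, and threshold 1 (the pivot
alone) needs no row at all. Quantiles that floor to 0 are dropped with a
warning. The labelling convention — *record label = certified minimum
count* — is this package's own; it makes the reported value directly
interpretable ("present in at least this many genomes") and is asserted
against exact queries in the tests.

## Interval-length filtering

A k-mer can only span-with-overhang a record of length at most $k - 2$.
Dropping non-gap records longer than $l$ therefore leaves every query with
$k \le l + 2$ bit-identical while shrinking the index; gap records are
always kept. The resulting index refuses larger $k$ with an error that
names the bound (e.g. $l = 29$ supports $k \le 31$). Losslessness over the
whole supported range is asserted fixture-wide.

## Storage

Records are persisted as a Parquet table — columns `contig`
(dictionary-encoded), `start`/`end` (int64), `label` (int32), `is_gap`
(bool) — every column ZSTD-compressed, with index metadata (pivot, genome
names, $t$, mode, contig lengths, filter bound, thresholds) embedded as
`panmem.*` keys in the footer so the file is self-describing. The
canonical sort (contig, start, end, label) keeps coordinate columns
non-decreasing within blocks, which is what columnar compression exploits;
all genomes/orders are interleaved in one file for the same reason. Row
groups default to about 0.5 GB of raw records (`chunk_bytes`), a size
aimed at genome-scale indexes; tests use small values to exercise
multi-group files. `read_region()` pushes the intersection predicate
($s \le q_{start} < e$ or $q_{start} < s < q_{end}$) into the Parquet scan
so non-matching row groups are skipped via column statistics.

A known floor: a standards-compliant Parquet file spends roughly 3–4 kB on
schema, statistics and footer. Below a few hundred records the plain-text
BED rendering can therefore be smaller than the index file; the advantage
reverses quickly (already ~4× in the index's favour on desk-scale
fixtures) and grows with size.

## The synthetic generator and what passing tests mean

`simulate_pangenome()` emulates a pangenome as a uniform-random pivot plus
independent mutated copies: per-base substitutions (uniform among the
three alternatives), insertions and deletions with geometric(0.5) lengths
capped at 50 bp, and non-overlapping 100–1000 bp segments replaced by
their reverse complement to create strand effects. Defaults (1%
substitutions, 0.1% indels, one inversion) sit in the range of
within-species divergence and reliably create MEM breakpoints, adjoining
MEMs, long shared stretches and strand flips. It does **not** model
coalescent structure, recombination, shared variants between copies, or
repeat families; since ground truth is defined by brute-force oracles
(`oracle_kmer_presence()`, `oracle_conservation()`) rather than by the
generator's internals, the oracle-equivalence results certify the *index
algebra* on any input of this alphabet — but say nothing about, e.g.,
runtime behaviour on repeat-dense real genomes.

Problem sizes in the shipped suite were chosen to exercise every code path
while keeping a full run in minutes on one core: twenty pangenomes with
$t \in \{2,3,5,10\}$, 5–20 kb pivots over 1–3 contigs, substitution rates
0.5–5%, queried exhaustively at $k \in \{4, 11, 21, 31, 64, 101\}$ against
the oracles, plus ~100 random pattern/text pairs ($m, n \le 200$) for the
matching-statistics brute force.

## Conventions and degenerate inputs

* All genomic intervals, regions and records are 0-based half-open; MS
  vectors are 1-based internally, with the fixed conversion *peak at $j$,
  height $\ell$ → $[j-\ell, j)$*.
* Sequences are uppercased on input; characters outside `A C G T N` are an
  error by default (`ambiguous = "N"` coerces). `N` is a literal character
  for matching — it matches only `N`, never acts as a wildcard — and is
  its own reverse complement. The oracles use the same rule, so
  equivalence is well-defined.
* Queries enumerate only k-mers fully inside the region
  ($x \in [start, end - k]$); `k` larger than the region is an error, as
  is `k > l + 2` on a filtered index.
* Empty pivots or targets are errors; an all-zero MS vector produces a
  single whole-contig gap record, and queries on it correctly report
  absence everywhere (conservation 1).
* Index construction is deterministic: identical inputs give identical
  record sets, and permuting the non-pivot input order changes nothing in
  conservation/quantile mode and only the genome-id labels in membership
  mode (both asserted).

## Limitations

* Queries are limited to k-mers present in the pivot, at pivot
  coordinates; a k-mer absent from the pivot is invisible no matter how
  conserved elsewhere. One index serves one pivot.
* The per-genome MS landscape cannot be reconstructed from an order-mode
  index: column sorting deliberately discards genome identity.
* Quantile indexes floor counts; they never overstate conservation but can
  understate it by up to the gap between adjacent thresholds.
* The suffix automaton holds the target text in memory during
  construction (linear, small constant); very large genomes cost RAM at
  build time, never at query time.
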