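---
title: "Space-time tiled Nussinov folding: model, schedule, and validation"
author: "SpaceTimeFold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time tiled Nussinov folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpaceTimeFold)
```

## The model

Nussinov's dynamic program predicts an RNA secondary structure by
maximizing the number of non-crossing complementary base pairs.  For a
strand $X = x_0, \dots, x_{N-1}$ over $\{A, U, G, C\}$ the $N \times N$
matrix $S$ is filled by

$$
S(i,j) = \max \begin{cases}
  S(i+1, j-1) + \sigma(x_i, x_j) \\
  \max_{i \le k < j} \big( S(i,k) + S(k+1,j) \big),
\end{cases}
$$

where $\sigma$ is 1 for an AU, GC or GU (wobble) pair and 0 otherwise.
$S(0, N-1)$ is the optimal pair count; a traceback recovers one optimal
pairing.  Two deliberate modelling points:

* **No minimum hairpin length.**  Adjacent bases may pair, exactly as the
  recurrence allows.  Thermodynamic folders typically forbid loops shorter
  than three unpaired bases; this maximum-matching model does not, so
  pair counts here are upper bounds on what such tools report.
* **Fail-fast alphabet.**  Only `AUGC` (plus `T` and lower case, which are
  normalized) are accepted.  IUPAC ambiguity codes are rejected at parse
  time rather than silently scored unpairable.

We index 0-based internally: $0 \le i < j \le N-1$, with the $i$ loop
descending.  User-facing base-pair tables are 1-based, following R
convention.

As a loop nest the recurrence is two statements over a triangular
iteration domain: the *split* statement `S1(i,j,k)` applies
`S[i][j] = max(S[i][j], S[i][i+k] + S[i+k+1][j])` for
$0 \le k \le j-i-1$, and the *pairing* statement `S2(i,j)` applies
`S[i][j] = max(S[i][j], S[i+1][j-1] + sigma(x_i, x_j))` after all splits
of its cell.  The global timestamp $(i, j, s, k)$ — $i$ compared
descending, statement ordinal $s$ = 0 for S1, 1 for S2 — encodes that
order; `stampOrder()` is the single place this sign convention lives.

## Engines

Three engines produce the same matrix; all three kernels are compiled
(Rcpp), which is where an $O(N^3)$ inner loop belongs:

* `foldReference()` — the original loop order, the correctness oracle.
* `foldTranspose()` — mirrors finished cells into the lower triangle so
  the split sum reads two row-contiguous operands, the classic
  cache-friendly reformulation for this kernel.
* `foldTiled()` — the space-time tiled schedule described next.

```{r engines}
s <- randomRna(150, seed = 7)
ref <- foldReference(s)
identical(scoreMatrix(foldTiled(s, ws = 16, wt = 16))[upper.tri(diag(150))],
          scoreMatrix(ref)[upper.tri(diag(150))])
```

## Why tiling this nest is hard, and the space-time answer

The nest's dependences are *non-uniform*: the split statement reads cells
at distances that grow with $j - i$, so classic affine tiling either
serializes the innermost loop (losing the main cache win) or produces
parameter-sized tiles.  The space-time construction bounds tiles in all
three dimensions:

1. **Space bands.**  Rows are cut into bands of width $W_s$ anchored at
   the top ($ii = \lfloor (N-1-i)/W_s \rfloor$, because $i$ descends), and
   the anti-diagonal $d = j - i$ into bands
   $d \in (W_s \cdot jj,\; W_s \cdot jj + W_s]$.  Along both band axes all
   dependence distances are non-negative (taking the decremented $i$ into
   account), so bands enumerate legally in lexicographic order.  The
   bands over $d$ follow the defining inequalities, not an axis-parallel
   picture: a tile is a segment of an anti-diagonal.
2. **Time slices.**  A space tile is still unbounded along $k$.  A slice
   index $tt = \lfloor k/W_t \rfloor$ for S1 and $\lfloor j/W_t \rfloor$
   for S2 cuts it into sub-tiles of at most $W_s \cdot W_t$ split
   instances.
3. **Skewing.**  The wavefront $w = ii + jj$ makes the outer dimension
   serial while tiles with equal $w$ and different $jj$ are independent —
   they may run in any order or on any number of threads.

Each instance maps to the 8-tuple $(w, jj, i0, tt, i, j, s, k)$, compared
lexicographically.  The ordinal $s$ resolves a genuine ambiguity: the
pairing statement has no $k$, so its natural tuple is shorter, and
appending $s$ (S1 = 0 before S2 = 1) fixes the order at an identical
prefix in the direction the data flows (S2 reads what every S1 of its
cell wrote).  Tile identity
is standardized on the parameter tuple $(ii, jj, i0, tt)$; boundary tiles
are clipped by the domain, never padded.

```{r tiles}
p <- tilingParams(40, ws = 16, wt = 16)
tileStats(p)
```

## Validation: brute force against the schedule

Rather than trusting the algebra, `validateSchedule()` checks it
exhaustively at concrete sizes.  `extractDeps(n)` enumerates every
ordered pair of instances touching a common cell with at least one write
— flow, anti and output alike, a deliberate over-approximation: any
schedule that orders all memory-based pairs also orders the value-based
subset a polyhedral legality test uses.  Pairs are found per cell
(grouping accesses by the cell they touch), which is equivalent to the
quadratic all-pairs scan but feasible up to the configured cap
($n \le 80$; the table grows like $n^4$).

```{r validate}
validateSchedule(tilingParams(20, ws = 4, wt = 4))
```

Two further cross-checks tie the machinery to the closed form: the
nest's dependence relation written as seven affine clauses
(`closedFormRMember()`) must admit only genuine ordered dependences, and
every brute-force flow dependence must lie in the transitive closure of
the clauses.  Both hold on every size the test suite enumerates
($n$ = 3..12).  We assert containment rather than set equality because a
closed-form relation of this kind may be value-based (last writer only),
while our extractor is deliberately memory-based.

The executor itself is tested three ways: elementwise equality with the
reference engine across lengths and widths, bit-identical results under
random permutation of same-wavefront tile order, and thread-count
invariance.  Correctness under concurrency is defined as "any
interleaving of same-wavefront tiles is valid" and tested by shuffling,
not by assuming a particular runtime.

## The free-schedule laboratory

`freeSchedule()` reproduces, in miniature, how time partitions arise: on
a box iteration space with constant distance vectors it assigns each
point the length of the longest dependence chain reaching it (earliest
start).  Points are relaxed in lexicographic order; with lexicographically
positive vectors one sweep suffices, but the loop iterates to a fixpoint
so it stays correct for any acyclic set, and a fixpoint not reached
within #points sweeps is reported as a cycle.  A point with no in-box
predecessor gets $t = 0$ even if it sits "late" in the box — that is the
free-schedule definition, not an accident.

```{r lab}
ex <- workedExample()
ex$partitions[[3]]                       # partition t2 of the 3x3x3 box
max(partitionIndex(ex$schedule))         # longest chain: 8
```

On this canonical $3^3$ box with vectors $(0,0,1), (0,1,0), (1,0,-1)$ the
earliest start coincides pointwise with the affine form $2i + j + k$ — an
emergent fact the tests confirm rather than assume.  `timeSlices()`
groups $W$ consecutive partitions into a slice; `checkSliceLegality()`
verifies no dependence crosses slices backwards.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `ws` | space band width (instances) | 16 | bounds a tile along $i$ and $d$; 16×16 keeps a tile's working set within a typical L1/L2 footprint |
| `wt` | time slice width (instances) | 16 | bounds a tile along $k$ (and $j$ for pairing); equal widths give near-cubic tiles |
| `threads` | workers for same-wavefront tiles | 1 | any value is correct; speed-up is hardware-dependent |
| `verifyCap` | bench verification length | 1000 | reference re-fold is $O(N^3)$; beyond this the harness times without re-checking |

Tile widths trade locality against parallel grain; they never affect the
result, only speed, and every width $\ge 1$ is legal.

## The synthetic generator and what passing tests show

`randomRna()` draws bases i.i.d. uniform over the four letters,
reproducibly per `(length, seed)` and without touching the global RNG
stream.  For *performance* questions this is the right surrogate: cache
behaviour of this kernel depends on strand length, not content.  For
*biological* questions it is not a model of anything — real RNA has
skewed composition and correlated structure — so passing equivalence and
validity tests says the engines compute the recurrence correctly on any
input, and nothing about predictive accuracy of the maximum-matching
model itself.  Benchmark timings (`runBench()`) are reported, never
asserted: they are properties of the machine.

## Problem sizes used by the checks

The test suite works at sizes chosen to exercise every boundary case
while staying exhaustive where exhaustiveness is the point: oracle
equivalence on ~200 strands of length 2–12 (where literal enumeration of
non-crossing matchings is feasible), engine equivalence on 30 strands per
length in {17, 64, 150, 301} across three width settings, schedule
validity at $n$ = 3..12, 20, 40, 60 for four width settings, and the
partition property at $n$ up to 200 for five width settings.  These are
the package's own verification sizes; the engines themselves handle
strands of many thousands of bases.

## Known limitations

* Maximum matching only: no thermodynamics (Zuker/McCaskill), no
  pseudoknots, no suboptimal ensembles.
* Dependence extraction and schedule validation are brute-force by
  design and capped; they certify concrete sizes, they are not a
  symbolic proof for all $N$.
* The closed-form dependence clauses are checked by containment, not set
  equality (see above).
* Traceback returns one optimal structure under a fixed tie-break
  (pairing case first, then smallest split), not all co-optima.
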