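# SpaceTimeFold

RNA secondary-structure prediction by Nussinov's maximum-base-pairing
dynamic program, together with a **space-time tiling** of its loop nest:
a tiled, wavefront-parallel execution schedule that is provably
equivalent to the textbook algorithm, plus the dependence-analysis
machinery to demonstrate that equivalence exhaustively.

It is aimed at two audiences at once: bioinformaticians who want a fast,
validated maximum-matching folder with FASTA in / dot-bracket out, and
people studying the parallelization of non-serial polyadic dynamic
programming, who get an executable model of the tiling — iteration
domains, dependences, distance vectors, tiles, schedules and their
validation — small enough to inspect.

## The algorithm

For a strand `x_0..x_{N-1}` over `{A, U, G, C}`, with `sigma(a, b) = 1`
for AU, GC, GU pairs (else 0):

    S(i,j) = max( S(i+1, j-1) + sigma(x_i, x_j),
                  max_{i <= k < j} S(i,k) + S(k+1,j) )

`S(0, N-1)` is the maximum number of non-crossing complementary pairs;
traceback recovers one optimal pairing.  Adjacent bases may pair (no
minimum hairpin length) — exactly what the recurrence allows.

Three engines fill the same matrix:

| engine | idea |
|---|---|
| `foldReference()` | original loop order (the oracle) |
| `foldTranspose()` | lower triangle mirrors the upper, so the split sum reads row-contiguous operands |
| `foldTiled()` | space-time tiles: row bands × anti-diagonal bands × time slices, executed along wavefronts `w = ii + jj`; same-wavefront tiles run in any order or on several threads |

The analysis side: `enumerateDomain()`, `extractDeps()` (brute-force
flow/anti/output dependences), `distanceVectors()`, `closedFormRMember()`
(the closed-form dependence relation), `validateSchedule()` (exhaustive
legality proof at a concrete size), and a free-schedule laboratory
(`depBox()`, `freeSchedule()`, `timeSlices()`) reproducing how time
partitions arise on a box with constant distance vectors.

## Worked example

```r
library(SpaceTimeFold)
fa <- tempfile(fileext = ".fa")
writeLines(c(">hairpin", "GGGAAAUCCC"), fa)
recs <- foldFasta(fa)
writeFoldResults(recs)
#> >hairpin
#> GGGAAAUCCC
#> ((((..))))
foldResultsTable(recs)
#>      name length score
#> 1 hairpin     10     4
```

Four non-crossing pairs: the three GC pairs of the stem plus one AU; the
two remaining loop bases stay unpaired.  The tiled engine gives the
identical matrix, and its schedule can be checked rather than believed:

```r
validateSchedule(tilingParams(20, ws = 4, wt = 4))
#> Schedule validation: N = 20, Ws = 4, Wt = 4
#>   dependences checked : 37317
#>   ordering violations : 0
#>   wavefront violations: 0
#>   schedule is VALID

tileStats(tilingParams(40, 16, 16))
#> Tile statistics: N = 40, Ws = 16, Wt = 16
#>   tiles: 207 across 5 wavefronts
#>   max instances per tile: 256 (S1 only: 256, bound ws*wt = 256)
```

Every dependence of the nest at N = 20 is ordered by the space-time
schedule and none links two tiles of the same wavefront — that is the
statement "tiles of a wavefront may run in parallel", verified by brute
force.  Tile size is bounded by `ws*wt` regardless of N.

See `vignettes/space-time-tiling.Rmd` for the full account of the model,
the tiling construction, and the design choices.

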