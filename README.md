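# fpsearch

Fast similarity search for dense binary molecular fingerprints in R.

Similarity search over substructure fingerprints is the workhorse of
cheminformatics: virtual screening, nearest-neighbor lookups in compound
registries, and clustering (e.g. Taylor–Butina, whose cost is dominated by
building a sparse all-pairs similarity matrix) all reduce to comparing one
bit vector against millions.  `fpsearch` is for anyone who has fingerprints
— from RDKit, Open Babel, OpenEye, CACTVS, or their own code — and needs to
read, write, and search them quickly from R.

## What it implements

For fingerprints with popcounts *A* and *B* and intersection popcount *c*,
the package searches on the **Tanimoto similarity**

    T = c / (A + B − c)

and the asymmetric **Tversky similarity**

    S = c / (α(A − c) + β(B − c) + c)

with these core pieces:

* **FPS format** — the line-oriented text exchange format (`#`-prefixed
  header, hex fingerprint + tab + id per line), with gzip transparency,
  total validation, and line-numbered errors.
* **FPB format** — a chunked binary container (META/AREN/POPC/FPID/HASH/
  FEND) with lazy, random-access loading and a cdb-style id hash.  A
  memory-budgeted collated writer builds large files from streams.
* **Fingerprint arena** — a contiguous, zero-padded, popcount-sorted block
  with a popcount bin index.
* **BitBound-pruned search** — threshold and k-nearest (heap and
  counting-sort variants), single query, multiquery, and symmetric N×N;
  a hit at threshold *T* must have popcount *B* in [*A·T*, *A/T*], so whole
  bins are skipped, and per bin a candidate needs
  *c* ≥ ⌈*T*(*A*+*B*)/(1+*T*)⌉ before any division.
* **Exact integer decisions** — thresholds become exact rationals *p/q*
  (every double is one), so the integer rejection test *c·q* ≥ *p·(A+B−c)*
  *is* the accept test; Tversky weights are scaled by 10,000 and rounded,
  making self-similarity exactly 1.0.  Floating point only produces the
  reported scores.
* **Streaming FPS scan search** — scores computed directly from hex text;
  k-nearest scans stop early after *k* exact matches.
* **Command-line tools** — `simsearch`, `fpcat`, `sdf2fps` equivalents
  (`inst/cli/*.R`, or the `cli_*()` functions).
* **Synthetic data + benchmark harness** — generators with uniform-density
  and exact popcount-histogram models, and an instrumented task suite that
  reports deterministic work counts (Tanimoto evaluations, divisions,
  bytes examined) alongside wall times.

See the methods vignette (`vignettes/fingerprint-search.Rmd`) for the
algorithms, numerical choices, and limitations.

## Worked example

```r
library(fpsearch)

targets <- synthetic_fingerprints(100000, num_bits = 2048, seed = 42)
ar <- fp_arena(targets)
ar
#> <fp_arena> 100000 fingerprints x 2048 bits (256 bytes/slot, popcount-sorted)

q <- fps_fingerprint(targets, 1234)      # use one record as the query
search_knearest(ar, q, k = 5)
#>   index       id      score
#> 1 53026  SYN1234 1.00000000
#> 2 67812 SYN74926 0.09677419
#> 3 10563 SYN13687 0.08333333
#> 4 77820 SYN87127 0.08333333
#> 5 19941 SYN75998 0.08139535

run_benchmark(ar, targets[1:100])
#>            task queries targets seconds n_tanimoto n_divisions bytes_examined
#> 1 threshold-0.4     100  100000   1.624    9999848         100     2559961088
#> 2    knearest-1     100  100000   0.093        281         281          71936
#> 3 knearest-1000     100  100000   2.426   10000000    10000000     2560000000
```

The query finds itself at exactly 1.0; everything else in this
independently generated set sits near the background similarity of sparse
2048-bit fingerprints (density 0.024), which is why the threshold-0.4 task
returns only self-matches.  The k=1 task shows the pruning at work: because
every query has an exact copy among the targets, the exact-match early exit
ends each search after a few hundred intersection popcounts instead of ten
million.  Scores are printed as doubles, but every accept/reject decision
behind them was made in integer arithmetic.

Ids round-trip through both formats:

```r
write_fps(targets, "targets.fps.gz")          # text, gzip by suffix
write_fpb(ar, "targets.fpb")                  # binary, fast to load
fpb <- read_fpb("targets.fpb")                # lazy: reads the directory
lookup_id(fpb, "SYN1234")                     # cdb hash lookup
#> [1] 53026
```

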