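---
title: "Methods: fingerprint similarity search in fpsearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint similarity search in fpsearch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpsearch)
```

# The model

A molecular fingerprint is a fixed-length binary bit vector encoding
substructure features of a molecule; two molecules are judged similar when
their fingerprints share many set bits.  The dominant comparison is the
Tanimoto (Jaccard) similarity

$$
T(\mathrm{fp}_1, \mathrm{fp}_2)
  = \frac{|\mathrm{fp}_1 \cap \mathrm{fp}_2|}{|\mathrm{fp}_1 \cup \mathrm{fp}_2|}
  = \frac{c}{A + B - c},
$$

where $A$ and $B$ are the population counts (numbers of set bits) of the
two fingerprints and $c$ is the popcount of their intersection.  The second
form matters operationally: when target popcounts are precomputed, each
comparison costs a single intersection popcount.  Two all-zero fingerprints
are defined to have similarity 0; this convention propagates everywhere
(searches, Tversky, file scans).

The Tversky similarity generalises this asymmetrically:

$$
S_{\alpha,\beta} = \frac{c}{\alpha (A - c) + \beta (B - c) + c},
$$

with $\alpha$ weighting the bits unique to the query and $\beta$ those
unique to the target.  The Tversky literature rarely writes the equation in
a single canonical form; this package adopts the form above — the standard
cheminformatics convention — with $\alpha = \beta = 1$ reducing exactly to
Tanimoto.

# Exact integer arithmetic

IEEE doubles are not distributive, and naive floating-point Tversky
implementations can return self-similarities slightly below 1.  The package
therefore makes **every accept/reject decision in integer arithmetic**;
floating point appears only in the final division that produces a reported
score.

* **Thresholds.**  Every finite double in $[0,1]$ is exactly an integer
  fraction $m/2^s$.  A threshold is decomposed that way and reduced to
  $p/q$ (with $q \le 2^{53}$, so both parts survive an R double), making
  the rejection test $c\,q \ge p\,(A+B-c)$ *equivalent* to
  $\mathrm{score} \ge T$ — the rejection test is also the final test, and
  no confirming division is needed.  Products are evaluated in 128-bit
  integer arithmetic in the C++ kernels.
* **Tversky weights** are capped at 10, scaled by 10,000 and rounded to
  integers before a search (values with more than four decimal digits are
  rounded with a warning — there is no chemically meaningful reason for
  more precision).  Self-similarity is then exactly 1 for any nonzero
  fingerprint.
* **Per-bin bound.**  For a popcount bin $B$, any hit must satisfy
  $c \ge \lceil T(A+B)/(1+T) \rceil$, computed as
  $\lceil p(A+B)/(p+q) \rceil$ in integers so floating-point error can
  never corrupt the ceiling.  Computed once per bin, the threshold test
  becomes one integer comparison.

## A deliberate knife-edge

Because the rational equals the *double* the user's text parses to, exact
semantics differ from "compare score doubles" semantics on a measure-zero
boundary.  The double of `0.4` is slightly **above** the real 2/5, so a
target scoring exactly 2/5 is *not* a hit at threshold `"0.4"` here, even
though `2/5` and `0.4` round to the same double.  (At `"0.7"`, whose double
sits slightly below the real 7/10, the two semantics agree.)  We chose
exactness: the hit set is a deterministic function of the parsed threshold
value, identical across compilers and platforms, and the documented parsing
rule — decimal text → nearest double → exact rational — makes expansions
like `0.7000000000000000070` behave identically to `0.7`.  The test suite's
oracles respect this by comparing in exact split-limb integers rather than
by double division.

# The arena and BitBound pruning

Fingerprints are stored in one contiguous block, each record zero-padded to
a storage size that is a multiple of 8 bytes so popcounts proceed 64 bits
at a time.  Records are sorted by popcount with a bin-boundary index
(`popcount_index[b]` … `popcount_index[b+1]-1` holds the records with
popcount `b`); the index stores all target popcounts implicitly and drives
the BitBound rule: a hit at threshold $T>0$ for a query of popcount $A$
must have $\lceil A\,T \rceil \le B \le \lfloor A/T \rfloor$, so whole bins
are skipped.  Unsorted arenas are supported (they preserve aggregation
order) and searched by a linear scan computing both popcounts.

k-nearest search visits bins in decreasing order of their best possible
score $\min(A,B)/\max(A,B)$ — a constant-memory merge of the two
monotonically decreasing sides below and above $A$ — and stops when the
current $k$-th best score strictly exceeds every unvisited bin's bound
(strictness preserves the tie-break; see below).  Two selection methods
return identical results: a bounded heap ($O(n \log k)$), and a counting
sort that buckets hits by their exact reduced score fraction — Tanimoto
scores are ratios of small integers with few distinct values, which removes
the $\log k$ factor for large $k$.

Numerical/ordering choices, all documented so oracles can assert them:

* Threshold hits are returned in ascending target index (file order for
  scans); k-nearest hits by descending score with ties broken by ascending
  target index.
* Result ranking comparisons between hits are done exactly on the integer
  pairs $(c, d)$, never on score doubles.
* Once $k$ hits of score exactly 1.0 are held, the search stops: score-1.0
  hits can only exist in the query's own bin, which is visited first in
  ascending index order, so no later candidate can displace them under the
  tie-break.  This mirrors the early-exit rule of the k-nearest file scan.
* An all-zero query scores 0 against everything: no hits at $T>0$; at
  $T=0$ (or k-nearest without a minimum) every target is eligible at
  score 0.
* Duplicate fingerprints and duplicate ids are never merged.

**Tversky search** uses a linear scan with the integer rejection test and
no popcount bound: the BitBound window is Tanimoto-specific, and we found
no published bound for asymmetric weights that we could verify, so
correctness wins over speed.  This is a known limitation.

The symmetric $N \times N$ search computes the upper triangle only —
in a sorted arena a row's partners at larger index lie in bins at or above
its own, clipped by the BitBound upper limit — and mirrors it, so the
result is symmetric, with an even entry count and no diagonal.  Parallel
execution (`workers`) partitions per-query work across forked processes
where available; results are independent of worker count and of the
optional popcount-grouping of query execution order, because queries are
independent and output is reassembled in input order.

# File formats

**FPS** is the line-oriented text format: an optional `#FPS1` version line,
`#key=value` metadata lines (`num_bits`, `type`, `software`, `source`
(repeatable), `date`), then one record per line — lowercase hex fingerprint,
tab, id, optionally further tab-separated fields that are preserved
verbatim on pass-through.  Bit $k$ lives in bit $k \bmod 8$ of byte
$\lfloor k/8 \rfloor$ (so the nibble order of a 16-bit fingerprint is
"1032"); decoding `"0100"` yields bit 0, `"2000"` bit 5, `"c218"` bits
{1, 6, 7, 11, 12}.  Bits at or above `num_bits` must be zero.  Reading
validates every line and reports errors with line numbers; unknown
`#key=value` lines are carried as extras and unparseable `#` lines as
opaque comments, so the format can grow without breaking readers.  Both
`\n` and `\r\n` are accepted; `\n` is written.  Empty ids are rejected —
the format description leaves this open, and a searchable record with no
name has no referent, so we fail early.  Gzip input is detected from magic
bytes, not the suffix.

**FPB** is this package's chunked binary dialect for fast loading: an
8-byte signature (`FPB1\r\n\0\0`, in the PNG tradition of embedding a
binary-transfer canary), then chunks of (u64 payload length, 4-byte tag,
u32 reserved) + payload, all little-endian, ending at `FEND`.  `META`
carries the FPS header text verbatim; `AREN` the contiguous fingerprint
block (with `num_bytes`, `storage_size`, and a spacer that aligns the
first fingerprint to 64 bytes when the storage size is a multiple of 64,
else to 8); `POPC` the popcount bin starts (present iff sorted); `FPID`
the UTF-8 ids with a u32 cumulative-offset table; `HASH` a classic
two-level cdb hash table (256-bucket pointer header, records, slot tables;
DJB-xor hash; duplicate ids as repeated keys) mapping id → record indices.
Unknown tags are skipped, so the format is extensible.  The 32-bit offsets
of the hash design cap the record count (practically a few hundred million;
this implementation additionally keeps counts below $2^{31}$, R's integer
range).  Lazy loading reads only the chunk directory and metadata;
fingerprints, ids and hash lookups resolve against the file on demand and
are cached.  **This dialect is not claimed to be wire-compatible with any
other tool's FPB files**; all round-trip guarantees are self-round-trip.

Collated writing (`write_fpb_collated`) spills popcount-sorted partial FPB
files whenever the accumulated fingerprint bytes reach the memory budget,
then collates them popcount bin by popcount bin with sliced file reads.
Because spills are merged in stream order and the sort is stable, the
output is byte-identical to a direct write of the whole set.  The budget
bounds the sorting working set; the final output block and the id list are
still materialised once during assembly — a deliberate desk-scale
simplification.

**File-scan search** computes scores directly from the hex text of each
line; no fingerprint object is materialised for sub-threshold lines.
Threshold scans validate the entire file even when nothing matches;
k-nearest scans may stop reading — and stop validating — once $k$ exact
(score 1.0) matches have been seen.  The Tanimoto threshold and k-nearest
scans are specialised this way; Tversky queries route through the arena
path instead of a dedicated scan.

# Synthetic data and the benchmark harness

The generator (`synthetic_fingerprints`) supports two density models:
uniform per-bit (every bit set independently with probability `density`)
and an exact popcount histogram (requested counts per popcount, realised
exactly with uniformly chosen bit positions).  Default densities by length
are 0.25 (166 bits, MACCS-like), 0.10 (881, PubChem-like), 0.05 (1021,
FP2-like path fingerprints, which are unusually sparse), and 0.024 (2048,
the measured bit density of Morgan fingerprints on drug-like collections).
Output is deterministic for a fixed seed; ids are sequential; duplicates
are kept.

`run_benchmark` executes the standard task suite — all matches at a
threshold (0.4 for sparse Morgan-like 2048-bit sets, where it selects
everything above background similarity; 0.7 otherwise) and k-nearest for
$k = 1$ and $k = 1000$ — and reports, per task, the wall time, the number
of Tanimoto evaluations (candidates surviving BitBound), the number of
integer-test passes requiring a score division, and the effective bytes
examined.  Counts are deterministic and are the asserted surface in tests;
times are hardware-dependent and never asserted.

**What the synthetic data does and does not emulate.**  Independently
drawn uniform-density fingerprints concentrate their popcounts tightly and
their best-match scores stay low, so BitBound has almost nothing to prune
in a $k=1$ search: candidate counts grow essentially linearly.  Real
collections are different in two ways that matter to pruning: popcounts
spread widely, and near-duplicates abound (a million-record MACCS
collection is typically well under 90% unique, and benchmark queries are
drawn from the same collection they search).  The sublinearity check
therefore samples targets **with replacement from a finite fingerprint
universe** (50,000 distinct 166-bit fingerprints at density 0.25) and
queries from the same universe: as the target set grows, more queries find
an exact copy and terminate via the early-exit rule, reproducing the
duplicate-driven part of the real sublinear scaling.  A passing check
shows that the pruning and early-exit machinery engage as designed; it
does **not** show that the hierarchical similarity structure of real
chemical space is reproduced, and measured exponents here should not be
compared to published ones.

**Problem sizes used by the test suite** (chosen once as desk-scale study
conditions): correctness oracles run 60 queries against 1,500 targets at
each of 166/881/1021/2048 bits across three thresholds and three $k$
values (over $2\times10^6$ query–target comparisons); Tversky
self-similarity uses $10^4$ fingerprints over an $\alpha,\beta$ grid;
format round-trips use $10^4$ records; the sublinearity check uses target
sets of $10^4$ to $10^5$ records with 100 queries.

# Known limitations

* No vendor-specific popcount intrinsics or CPU dispatch: the production
  kernel is a portable 64-bit word loop; `lookup8` and `bitwise` kernels
  exist as oracles.  All kernels return identical values by contract.
* No sharper pruning (M = 2 bounds, xor signatures, trees, reference
  points) and no Morton-order multiquery traversal.
* Tversky searches are unpruned linear scans.
* FPB files are a self-described dialect, not wire-compatible with other
  tools; per-record extra FPS fields are not stored in FPB.
* Sparse and count fingerprints are out of scope; fingerprints are dense
  fixed-length bit vectors throughout.
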