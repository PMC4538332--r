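---
title: "Tiled Smith-Waterman search: model, memory discipline, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiled Smith-Waterman search: model, memory discipline, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilesw)
```

## The problem and the model

Searching a protein database asks, for one query sequence $S_1$ of length
$L_1$ and each of $N$ subject sequences $S_2$ of length $L_2$, for the
optimal *local* alignment score: the best-scoring alignment of any
substring of $S_1$ against any substring of $S_2$. Residue pairs are scored
by a symmetric integer substitution matrix $\mathrm{sbt}(a,b)$ (BLOSUM62 by
default), and gaps carry an affine penalty: a gap of length $g$ costs
$\rho + g\sigma$ with open penalty $\rho$ and per-residue extension
$\sigma$.

`tilesw` computes this score with the three-matrix Gotoh recurrences, for
$1 \le i \le L_1$, $1 \le j \le L_2$:

$$
\begin{aligned}
E(i,j) &= \max\{E(i,j-1) - \sigma,\; H(i,j-1) - \rho - \sigma\}\\
F(i,j) &= \max\{F(i-1,j) - \sigma,\; H(i-1,j) - \rho - \sigma\}\\
H(i,j) &= \max\{0,\; E(i,j),\; F(i,j),\; H(i-1,j-1) + \mathrm{sbt}(S_1[i], S_2[j])\}
\end{aligned}
$$

with borders $H(\cdot,0) = H(0,\cdot) = 0$ and
$E(i,0) = F(0,j) = -\infty$. The reported score is $\max_{i,j} H(i,j)$;
no traceback is produced — database search ranks subjects by optimal
score only.

Two initialization details are genuinely open in compact presentations of
these recurrences and were fixed here as follows. First, whether $\sigma$
applies to the gap-extension branch inside or outside the max is
typographically ambiguous in some sources; we use the standard Gotoh form
above, which is the unique reading consistent with "open costs $\rho$,
each extension costs $\sigma$". Second, border values of $E$ and $F$ are
not universally stated; we use a large negative sentinel
($-2^{28}$, safe from 32-bit wrap-around after one subtraction) so an
alignment can never begin inside a gap.

## Two engines, one score

The package deliberately contains two independent implementations:

* `sw_reference()` — the naive full-matrix DP with rolling rows. It is the
  correctness oracle and the fallback path.
* `sw_tiled()` — the tiled engine, which computes exactly the same cell
  values but in the traversal order and through the memory structure of a
  GPU short-query kernel.

The contract is bit-exact score identity on *every* input, and the test
suite enforces it on 1000+ seeded random pairs across two matrices and
three gap models, plus an independent third route
(`Biostrings::pairwiseAlignment`) and, at desk scale, a brute-force
enumerator of all local alignments.

## The tiled engine and its memory model

The DP matrix is cut into tiles of $K$ subject residues by $P$ query
residues (defaults $K = P = 4$). Tiles are traversed in **column-major
order**: all tiles sharing one group of $K$ subject residues are processed
top to bottom before moving right. Within a tile, each of the $P$ query
residues is aligned against the $K$ subject residues left to right.

Dependences are carried through two distinct structures, mirroring the
register file and shared memory of a streaming multiprocessor:

* **Row carries (registers).** For each of $H$ and $F$, $K$ values of the
  current row are held in a $K$-register model and reused row after row;
  the $P$-th row of a tile flows to the tile below through these
  registers at no memory cost.
* **Column carries (shared buffer).** The $K$-th-column values of $H$ and
  $E$ cannot stay in registers (they are overwritten by the next row), so
  they are spilled, one $(H, E)$ pair per query row, to a per-lane column
  buffer. The tile column to the right reads them back as its left
  boundary. Because traversal is column-major, one buffer of
  $Q$ entries per matrix is reused across all tile columns.

`sw_tiled()` instruments this structure: `buffer_reads`/`buffer_writes`
count spills (exactly $2 Q_{\mathrm{pad}}$ per tile column — one $H$ and
one $E$ per row), `peak_buffer_bytes` is $4 Q_{\mathrm{pad}}$ (two
matrices at 2 bytes per cell), and an advisory `overflow` flag is raised
whenever a buffered value leaves the signed 16-bit range that 2-byte
cells imply. Scores are always computed in wide integers, so the flag
reports a fidelity boundary without corrupting results.

$F$ is deliberately *not* buffered at column boundaries: $F(i,j)$ depends
only on row $i-1$ of the same column, so it crosses tile rows (via
registers), never tile columns. Only $H$ and $E$ need the shared buffer,
which is what makes the budget below a factor of 4 rather than 6.

### Padding

Queries are padded to a multiple of $P$, subjects to a multiple of $K$,
with a reserved sentinel residue (`?`, never a matrix letter). Padded
positions score $-2^{20}$ against everything: negative enough that no
local alignment through a pad cell can ever rise above an existing score
(since $H \ge 0$ and all carried values only decay through gaps), small
enough never to overflow 32-bit arithmetic. Padding neutrality is tested
directly.

## The shared-memory budget and dispatch

With $S$ bytes of shared memory per multiprocessor divided among $T$
threads, buffering $H$ and $E$ at 2 bytes per cell costs 4 bytes per
buffered query position per thread, so the tiled path serves queries up to

$$Q_{\max} = \left\lfloor \frac{S}{4T} \right\rfloor$$

residues. At the classic configuration $S = 16384$, $T = 256$ each thread
owns 64 bytes (16 words) and $Q_{\max} = 16$. `dispatch()` selects the
tiled path iff the query fits; longer queries take the reference engine,
as do subjects beyond the intertask `length_threshold` (default 3072),
standing in for a cooperative multi-thread long-sequence kernel that is
out of scope here. A related budget form compares $S$ against
$T \times Q$ without the byte factor; we use the conservative
4-bytes-per-position rule throughout, since it is the one that accounts
for both buffered matrices at 2 bytes per cell.

## Database layout and load balance

One lane scores one subject sequence, and 32 lanes run in lock-step (a
warp): a warp is busy until its slowest lane finishes. Two preprocessing
steps model the standard remedies:

* **Ascending length sort** (`sort_by_length()`), so the 32 sequences
  sharing a warp have similar lengths.
* **Interleaving** (`interleave_group()`): residue $i$ of lane $k$ is
  stored at flat position $32i + k$, so lock-step lanes reading their
  $i$-th residues touch consecutive memory.

`warp_makespan()` accounts for the cost in DP cell updates (lane cost
$= L_1 L_2$; paid cost $= 32 \times \sum_w \max_{\text{lane}} L_1 L_2$), a
portable surrogate for wall-clock time — hardware throughput (GCUPS) is
deliberately not modeled beyond the `gcups()` unit conversion, and
occupancy effects such as one-block-per-multiprocessor contention are
reported qualitatively, not simulated.

One exact result worth stating carefully: with **complete warps** ($n$ a
multiple of the warp size), ascending sort minimizes the summed warp
makespans over all lane orders — adjacent grouping of a sorted list
maximizes the sum of per-group minima, and the tests verify minimality by
exhaustive permutation at warp size 2. When the final warp is incomplete
and padded with idle lanes, this global optimality can fail: ascending
order strands the longest sequence alone with idle lanes, and, e.g., for
lengths $\{10,20,30,40,50\}$ at warp size 2 a different order is strictly
cheaper. Sorting remains the right practical choice (it also bounds each
warp's length spread), but the permutation-optimality claim is only exact
for complete warps, and the test suite states it that way.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `rho` | 10 | score units | common BLOSUM62 gap-open pairing |
| `sigma` | 2 | score units / residue | common BLOSUM62 gap-extension pairing |
| `K` | 4 | subject residues / tile | keeps the register carry model small |
| `P` | 4 | query residues / tile | must be a multiple of 4: the packed profile delivers 4 scores per fetch |
| `shared_bytes` | 16384 | bytes | 16 KiB multiprocessor configuration |
| `threads_per_block` | 256 | threads | classic block size; gives $Q_{\max} = 16$ |
| `warp_size` | 32 | lanes | lock-step width; overridable only for desk-scale tests |
| `length_threshold` | 3072 | residues | intertask/intratask cutoff; longer subjects go to the reference engine |

## The synthetic corpus generator

`synth_protein_db()` draws sequence lengths from a log-normal law
(default `meanlog = log(300)`, `sdlog = 0.45`, clamped to 25–2000
residues), mimicking the right-skewed length distribution of curated
protein databases, with residues uniform over the 20 standard amino
acids. A uniform length law is available for controlled fixtures. The
generator is fully seeded, so every corpus in the tests and the
acceptance script is reproducible.

What it does *not* emulate: real residue composition (uniform letters
have no low-complexity regions or compositional bias), homology (no
planted motifs — scores against random subjects are near the noise
floor), and real database scale. Passing tests therefore demonstrate
score correctness, layout identities, and load-balance accounting — not
retrieval sensitivity on biological data, which depends only on the
scoring model already fixed by the matrix and gap parameters.

## Problem sizes used by the checks

The bundled verification runs use desk-scale sizes chosen to exercise
every boundary: 1000 random pairs with queries up to $Q_{\max} = 16$ and
subjects up to 512 residues for engine identity; exhaustive permutation
enumeration up to 8 lengths for warp optimality; 50 randomized groups for
layout round-trips; and a 200-sequence log-normal corpus for the
end-to-end search demo. All complete in seconds on one CPU.

## Known limitations

* Scores only — no traceback, CIGAR, or E-value statistics.
* Protein alphabets only; no DNA matrices or position-specific scoring.
* The long-sequence path is the serial reference engine, not a
  cooperative multi-lane kernel.
* The cost model counts cell updates; it does not predict wall-clock
  throughput on any particular hardware.
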