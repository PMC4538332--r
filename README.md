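# tilesw

Smith-Waterman local alignment search of protein databases, implemented
the way GPU short-query kernels organize the computation — and testable on
any CPU.

## What it is for

Given a query sequence and a FASTA database of subject sequences, `tilesw`
computes the optimal local alignment score of the query against every
subject under the affine-gap Gotoh recurrences

```
E(i,j) = max( E(i,j-1) - s,  H(i,j-1) - r - s )
F(i,j) = max( F(i-1,j) - s,  H(i-1,j) - r - s )
H(i,j) = max( 0, E(i,j), F(i,j), H(i-1,j-1) + sbt(S1[i], S2[j]) )
```

with gap-open penalty `r`, gap-extension penalty `s`, and a substitution
matrix `sbt` (bundled BLOSUM62/BLOSUM50, or any NCBI-format file), and
ranks the subjects by score. It is aimed at people studying *how* such
searches map onto lock-step hardware: alongside a naive full-matrix
reference engine it provides a tiled engine that reproduces, instruction
order and memory structure included, the discipline of a GPU short-query
kernel:

* ascending length sort and 32-lane interleaved database layout
  (residue `i` of lane `k` at flat position `32*i + k`);
* a packed query profile delivering 4 scores per fetch;
* column-major `K x P` tiling with register row carries and an explicit
  shared-memory column buffer for `H` and `E` (2 bytes per cell),
  instrumented with read/write/occupancy counters;
* the budget law `Q_max = floor(S / (4*T))` deciding whether a query takes
  the tiled path or the reference fallback;
* a warp load-balance simulator costing orders in DP cell updates.

The two engines are bit-exact score-identical on every input — that
identity, not wall-clock speed, is the package's core claim, and the test
suite enforces it against a brute-force enumerator and an independent
aligner.

## Worked example

```r
library(tilesw)

b62 <- load_matrix("blosum62")
g   <- gap_model(rho = 10, sigma = 2)

sw_reference("HEAGAW", "PAWHEA", b62, g)
#> [1] 17
r <- sw_tiled("HEAGAW", "PAWHEA", b62, g)
r$score
#> [1] 17
str(r$stats)
#> List of 6
#>  $ buffer_reads     : num 32
#>  $ buffer_writes    : num 32
#>  $ peak_buffer_bytes: num 32
#>  $ cells            : num 64
#>  $ tile_cols        : int 2
#>  $ overflow         : logi FALSE
```

Both engines score the best local alignment of `HEAGAW` vs `PAWHEA`
at 17 (the `AW` match plus flanking residues under BLOSUM62). The stats
show the tiled engine's memory model: the 6-residue query is padded to 8
rows, the subject to 8 columns (2 tile columns of width 4), each tile
column spilling one `H` and one `E` value per row to the shared column
buffer (2 x 8 x 2 = 32 writes), with a peak buffer of 4 bytes per query
row (32 bytes).

A full search from the shell:

```sh
exec/tilesw makedb --n 200 --out db.fasta --seed 3
printf '>q\nMKVAWHE\n' > q.fasta
exec/tilesw search --query q.fasta --db db.fasta --out hits.tsv
#> query q: 7 residues; database: 200 sequences
#> budget: S=16384 bytes, T=256 threads, Q_max=16 residues
#> path: tiled_short_query
#> wrote 200 rows to hits.tsv
```

`hits.tsv` lists `rank`, `subject_id`, `subject_length`, `score` in
descending score order (ties broken by id). A 7-residue query fits the
16-residue budget of the 16 KiB / 256-thread configuration, so the tiled
path serves it; a query over 16 residues would be logged and scored by
the reference fallback instead.

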