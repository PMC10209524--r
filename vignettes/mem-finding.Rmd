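---
title: "Maximal exact match finding with coprime sampling"
author: "memfindr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximal exact match finding with coprime sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfindr)
```

## The problem

A *maximal exact match* (MEM) between a reference genome $R$ and a query
genome $Q$ is an exact substring match that cannot be extended by one
character on either side — the flanking characters mismatch, are ambiguous,
or run off a sequence boundary. MEMs of a minimum length $L$ are the
anchors used to seed whole-genome alignments and genome-to-genome
comparisons. Enumerating them exactly is the whole game: a missed MEM can
silently corrupt an alignment chain, so this package treats completeness
and soundness as hard contracts and tests them against an independent
brute-force oracle.

## The sampling model

The finder indexes only every $k_1$-th position of $R$ (a hash table over
the $K$-mers starting there) and probes only every $k_2$-th position of
$Q$. Write a common substring of length $\ell \ge L$ as aligned windows
starting at $(a, b)$. Among the offsets $t = 0, \dots, k_1 k_2 - 1$ there
is, because $\gcd(k_1, k_2) = 1$, exactly one $t$ with
$a + t \equiv 0 \ (\mathrm{mod}\ k_1)$ and
$b + t \equiv 0 \ (\mathrm{mod}\ k_2)$ (Chinese remainder theorem over the
alignment shift $a - b$). If

$$k_1 k_2 \le L - K + 1,$$

that offset still leaves $K$ characters inside the window, so every MEM of
length $\ge L$ contains a sampled, aligned seed and is found. The test
suite verifies this exhaustively over all alignment residues for every
parameter pair in scope, and end-to-end by comparing the engine's distinct
output with the oracle's.

### Parameter policy

Given $L$ (minimum 37), the seed length is chosen as $K = 36$ for $L < 80$,
$44$ for $80 \le L < 200$, and $56$ for $L \ge 200$; memory-frugal mode
caps $K$ at 44. These thresholds are a policy reconstructed to reproduce
the published parameter tuples at $L = 50$, $80$, $132$ and $200$; they are
overridable (`seed_length`), and we flag explicitly that the drop to
$K = 44$ at intermediate $L$ is a reconstruction, not a first-principles
optimum. With budget $B = L - K + 1$, the base step is the largest $k$ with
$k(k-1) \le B$ and $k_2 = k - 1$ (consecutive integers are coprime); $k_1$
is then relaxed upward to the largest $j$ with $j \cdot k_2 \le B$ and
$\gcd(j, k_2) = 1$. Relaxation only ever helps: fewer reference positions
are indexed at identical sensitivity ($(6,5) \to (7,5)$ at $L = 80$,
$(9,8) \to (11,8)$ at $L = 132$).

## Genome representation

Sequences are uppercased and concatenated with a single `>` byte between
consecutive records. Matching requires *equal and unambiguous* characters
(`A/C/G/T` only), so the separator — like `N` and the other IUPAC codes —
never matches even itself, and no match can cross a sequence boundary; one
separator byte therefore suffices. Soft-masking (lowercase) is not treated
specially. Zero-length input sequences are dropped with a warning, since
they would force the predecessor step to zero. Internal coordinates are
0-based and absolute over the concatenation; output coordinates are
1-based and relative to the containing sequence.

## Seed index

The index stores every position $p \equiv 0 \ (\mathrm{mod}\ k_1)$ whose
$K$-mer is clean (all `A/C/G/T`). The hash is a fixed multiply-xorshift
over the 2-bit base codes — deterministic across runs and platforms — with
the top $b$ bits selecting among $2^b$ buckets,
$b = \min(2\lceil\log_2 n\rceil, 26)$ for $n$ sampled slots (memory-frugal:
$b - 2$). Buckets are laid out as parallel (bucket id, position) vectors
sorted by bucket with an equal-range lookup, rather than a dense
$2^b$-cell table: the memory then scales with the number of stored seeds,
which is the right trade at the scales this package targets. Collisions
are possible and expected; the scan always verifies the $K$-mer text before
extending, and buckets are never capped — completeness is contractual.

## Scan, extension and the containment filter

For each probed query position the candidates are verified, extended
maximally, and kept if the run reaches $L$. A per-diagonal cache remembers
the most recent MEM on each diagonal $d = r_{\mathrm{start}} -
q_{\mathrm{start}}$; a candidate seed wholly inside the cached interval on
its own diagonal is skipped. This is lossless by construction — extension
of a contained same-diagonal seed reproduces exactly the cached MEM —
whereas any cross-diagonal notion of containment would discard genuine
MEMs, which is why the filter is keyed by exact diagonal. The cache is
cleared at each query-sequence boundary. On near-identical genomes the
filter removes almost all redundant extensions; the suite asserts the
output is identical with the filter on and off.

The same MEM can still be emitted several times (several seeds inside one
long match, or across scan chunks); deduplication is the collator's job.
The `workers` knob partitions the sampled query positions into contiguous
chunks, each with its own cache, currently executed sequentially: the
package's contract — tested — is that the final output is byte-identical
for any worker count, which leaves the execution model free. Because each
chunk extends over the full text and chunk boundaries partition the
*sampled* positions exactly, no boundary overlap is needed and no seed is
ever missed at a chunk edge.

## Constant-time predecessor queries

Output conversion needs, per match, the last sequence start at or before
an absolute position. With $\ell_{\min}$ the shortest sequence length, the
genome is sampled at step
$s = 2^{\lfloor\log_2 \ell_{\min}\rfloor}$ (powers of two replace division
by shift); cell $c$ of the array `Beg` (length
$\lceil(|G| + 0.5)/s\rceil$) holds the record containing position
$c \cdot s$. Since $s \le \ell_{\min}$, at most one record boundary falls
inside a cell, so a query reads one cell and checks at most one successor —
equivalent to, and tested against, binary search. The builder accepts any
valid step so the published worked example (starts 0, 4, 7, 13, 17, 27,
32; step 3; queries 17, 14, 12) is directly testable; that example has no
separator gaps, so the builder deliberately requires only a records table,
not the concatenated layout. A degenerate guard (default $2^{27}$ cells)
falls back to binary search with a warning when $\ell_{\min}$ is tiny
relative to the genome; this only costs speed. The same structure is built
for the query genome, whose output coordinates need the identical
conversion.

## Collation: blocks, spills, rescue, merge

Output must be ordered by query position, then reference position, per
query sequence. The emitted stream is *nearly* sorted, so the collator
keeps a buffer of `match_block` triples (default $2^{21}$; memory-frugal
divides by 4): on overflow it sorts the buffer, spills the first three
quarters to a per-worker, per-sequence temporary file (skipping duplicates
of the previous or last-spilled triple), and retains the last quarter as
overlap. If a later block's smallest key sorts before the last spilled key
— possible in principle, rare in practice — a *rescue* re-reads the
sequence's spill, merges with memory, fully re-sorts, deduplicates,
rewrites the file and warns, suggesting a larger block; correctness never
depends on the overlap sufficing. Sorting uses a comparison sort up to
`sort_threshold` (default 1024) items and above that an LSD radix sort
over the six most significant bytes of the 80-bit packed
(qStart, rStart) key finished by comparison sort inside equal-prefix runs;
a single radix implementation stands behind the method knob, since
selecting between radix variants by cache size and thread count is
hardware tuning outside this package's scope. Finally the per-worker files
are k-way merged with cross-file deduplication and written as
MUMmer-family text: a `> name` header per query sequence (also when it has
no MEMs), then one tab-separated line per MEM with reference name, 1-based
reference position, 1-based query position, and length.

The suite pins the whole path to an independent in-memory reference
(full sort + dedup + conversion) and asserts byte-identical output across
`match_block` in {8, 64, $2^{21}$}, 1/2/4 workers, filter on/off, and both
memory modes.

## Synthetic data and the oracle

The generator produces i.i.d. uniform `ACGT` sequences; the mutation model
applies, per record and deterministically per seed, point substitutions at
a configurable rate, short insertions and deletions (lengths uniform up to
`max_indel_len`, default 10), and runs of `N`. This emulates the
same-species, highly similar regime (two human assemblies, say) where the
containment filter matters, and the multi-sequence layout with short
"runt" sequences that stresses the predecessor structure. It deliberately
does *not* model rearrangements, transpositions, CNVs or realistic base
composition — so passing tests demonstrate the string-algorithmic
contracts (completeness, maximality, ordering, determinism) on realistic
divergence levels, not biological realism of the fixtures themselves.

The oracle walks every diagonal of the $(R, Q)$ grid and records maximal
runs of matching characters of length $\ge L$ — exact, duplicate-free, and
independent of every mechanism it checks (no hashing, no sampling, no
extension logic). Its cost is $|R|\cdot|Q|$ character comparisons, guarded
by `max_cells` (default $10^8$); the compiled kernel makes occasional
larger runs practical by raising the budget explicitly, which is how the
100 kb fixture is checked. A generalized suffix-structure oracle for much
larger fixtures was considered and not built: the diagonal scan is obviously
correct, which is the property an oracle must maximize.

### Problem sizes used in the checks

The fixture grid pairs two-sequence genomes of 4.5 kb per sequence
(9 kb per genome) at divergences 0, 0.1%, 1% and 10% with
$L \in \{37, 50, 80, 132, 200\}$ and three seeds each, plus one 100 kb
pair at 1% divergence — sizes at which the quadratic oracle is exact and
fast while still exercising every parameter regime, multi-sequence
layouts, indels and ambiguity runs.

## Numerical and degenerate-input choices

* Coordinates are carried as R doubles (exact integers below $2^{53}$);
  the packed sort key allots 40 bits per coordinate and errors on
  overflow rather than wrapping.
* Ties in the output order can only arise as identical (qStart, rStart)
  pairs, which maximality forces to be identical triples; they are
  deduplicated, so no tie-break rule is needed.
* A query shorter than $K$, or containing no unambiguous bases, yields an
  empty (but well-formed, headers included) output.
* `L` below 37 is rejected with a clear message: 37 is the smallest
  minimum MEM length for which the shortest supported seed (36) leaves a
  sampling budget of at least 2.
* The hash, the scan order and the collation are all deterministic, so a
  run is reproducible bit-for-bit; randomness exists only in the synthetic
  generator, always behind an explicit seed.

## Known limitations

* Forward-strand matches only: no reverse-complement matching, and no
  MUM/MAM uniqueness classes.
* The scan chunks run sequentially in-process; the worker knob fixes the
  partitioning semantics (and is what the determinism contract is tested
  against) but does not yet buy wall-clock parallelism.
* FASTA only (no FASTQ, no transparent gzip); genomes are held in memory
  uncompressed.
* The seed-length-from-L thresholds are a documented reconstruction;
  `--seed-len` overrides them when a different trade-off is wanted.
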