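# memfindr

Finds all **maximal exact matches (MEMs)** of a user-chosen minimum length
*L* between two multi-FASTA genomes. A MEM is an exact match between the
reference *R* and the query *Q* that cannot be extended by a single
character on either side without hitting a mismatch, an ambiguity code, or
a sequence boundary. MEMs are the standard anchors for whole-genome
alignment and comparison (the MUMmer / E-MEM tool family), and the package
is written for people who need those anchors reproducibly at desk scale:
genome comparisons, alignment seeding, and validation of MEM-finding
pipelines.

## The method

The core is a seed-and-extend scheme with **coprime sparse sampling**:

* a hash table is built over the K-mers starting at every k1-th position of
  *R*;
* every k2-th position of *Q* is probed against it; candidates are verified
  textually, then extended maximally left and right;
* with gcd(k1, k2) = 1 and

  ```
  k1 * k2 <= L - K + 1
  ```

  every common substring of length >= L contains an aligned position pair
  sampled on both sides with at least K characters remaining (a
  Chinese-remainder argument over the alignment shift), so no MEM of length
  >= L is missed despite indexing only a 1/k1 fraction of *R* and probing a
  1/k2 fraction of *Q*.

Around that core the package provides:

* automatic selection of the seed length K from L, and relaxation of k1 to
  the largest value coprime with k2 under the budget (reproducing the
  published tuples (5,3,36), (13,11,56), (13,12,44), (7,5), (11,8));
* a **diagonal containment filter** that skips candidate seeds lying wholly
  inside a MEM already found on the same diagonal — losslessly — which is
  what makes comparisons of highly similar genomes fast;
* a **constant-time predecessor structure**: the genome is sampled at a
  power-of-two step bounded by the shortest sequence length, so mapping an
  absolute match position to its containing sequence needs one array cell
  and at most one successor check instead of a binary search;
* **block-wise collation**: matches are buffered, sorted (comparison sort
  for small blocks, an LSD-radix/comparison hybrid above a threshold),
  spilled to temporary files three quarters of a block at a time with a
  quarter-block overlap, rescued on the rare order violation, k-way merged
  with deduplication, and written in the MUMmer-family per-query text
  format;
* a synthetic genome generator (substitutions, indels, N runs) and an exact
  brute-force oracle used throughout the test suite.

## Worked example

```r
library(memfindr)
r   <- generate_genome(2, c(4000, 3000), seed = 1)              # reference
q   <- mutate_genome(r, mutation_model(substitution_rate = 0.01, seed = 2))
res <- find_mems(r, q, L = 50)
res
#> <mem_result> 48 MEM(s) of length >= 50 (2 ref / 2 query sequence(s); K=36, k1=5, k2=3)
summary(res)
#> MEMs: 48  (L >= 50, mode default)
#> length: min 50, median 95, max 370
#>   seq1: 28 MEM(s)
#>   seq2: 20 MEM(s)
#> seeds probed: 2310; candidates: 313; verified: 50; emitted: 48; rescues: 0
head(res$matches, 3)
#>   query ref_name ref_pos q_pos length
#> 1  seq1     seq1       1     1     50
#> 2  seq1     seq1      52    52    370
#> 3  seq1     seq1     423   423    118
```

A 1% point-substitution copy of a 7 kb two-sequence genome breaks into 48
MEMs of length >= 50; positions are 1-based and relative to the containing
sequence, exactly as in the output file written by `out =` or the
command-line driver:

```sh
exec/memfind ref.fa query.fa -l 50 -o out.mems [-t 4] [-mf]
exec/memfind fixtures --out-dir fx --length 10000 --divergence 0.01
```

The `-mf` (memory-frugal) flag shrinks the hash table and buffers and caps
the seed length; like the thread/worker count and the containment filter it
never changes the output, only the resources used.

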