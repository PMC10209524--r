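Package: memfindr
Title: Maximal Exact Match Finding Between Genomes via Coprime K-mer Sampling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Finds all maximal exact matches (MEMs) of a user-chosen minimum
    length between two multi-FASTA genomes using a seed-and-extend scheme in
    which only every k1-th reference position is indexed and every k2-th query
    position is probed, with k1 and k2 coprime so that every sufficiently long
    match is guaranteed to contain an aligned sampled seed. Includes automatic
    seed-length and sampling-step selection, a constant-time sampled
    predecessor structure for mapping absolute match coordinates back to
    sequence-relative ones, a diagonal containment filter that makes
    comparisons of highly similar genomes fast, block-wise sort-and-spill
    collation of matches with a rescue path, a synthetic genome generator and
    a brute-force oracle for validation, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
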