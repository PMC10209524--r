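#' Sampled k-mer seed index over the reference
#'
#' A hash table over the K-mers starting at every k1-th reference position.
#' Buckets are realized as two parallel vectors (bucket id, position) sorted
#' by bucket id with positions increasing within a bucket; a lookup is an
#' equal-range search. Collisions are possible by construction, so callers
#' must verify textual equality before extending (done in the scan).
#'
#' @name seed_index
NULL

#' Hash a K-mer to a bucket id
#'
#' A multiply-xorshift hash over the 2-bit encoding of the k-mer, fixed for
#' reproducibility: deterministic and identical across runs and platforms.
#' The top `bucket_bits` bits of the 64-bit hash select the bucket.
#'
#' @param kmer a string over A/C/G/T.
#' @param bucket_bits number of bucket-index bits (0 means a single bucket).
#' @return Bucket id in `[0, 2^bucket_bits)`.
#' @export
hash_kmer <- function(kmer, bucket_bits) {
  stopifnot(is.character(kmer), length(kmer) == 1L, nchar(kmer) >= 1L,
            bucket_bits >= 0, bucket_bits <= 30)
  if (grepl("[^ACGT]", kmer))
    stop("k-mer contains a non-ACGT character")
  cpp_hash_kmer(kmer, as.integer(bucket_bits))
}

#' Default number of bucket-index bits
#'
#' `min(2 * ceiling(log2(n_sampled)), 26)`, where `n_sampled` is the number
#' of sampled reference slots; memory-frugal mode uses two fewer bits (a
#' smaller table, more collisions, identical results).
#'
#' @param n_sampled number of sampled positions (slots) in the reference.
#' @param mode `"default"` or `"memory-frugal"`.
#' @return Integer bucket bits.
#' @export
default_bucket_bits <- function(n_sampled, mode = c("default", "memory-frugal")) {
  mode <- match.arg(mode)
  b <- min(2L * as.integer(ceiling(log2(max(n_sampled, 2)))), 26L)
  if (mode == "memory-frugal") b <- max(b - 2L, 2L)
  b
}

#' Build the seed index over a reference genome
#'
#' Stores every absolute position p with `p %% k1 == 0`, `p + K <= |R|` and a
#' K-mer made only of A/C/G/T (seeds spanning a separator or ambiguity code
#' are skipped). No bucket capping: completeness is contractual.
#'
#' @param R reference `mem_genome`.
#' @param p a [mem_params()] object.
#' @param bucket_bits bucket-index bits; default [default_bucket_bits()].
#' @return An object of class `seed_index`.
#' @export
build_seed_index <- function(R, p, bucket_bits = NULL) {
  stopifnot(inherits(R, "mem_genome"), inherits(p, "mem_params"),
            !is.null(R$text))
  n_slots <- max(0L, (R$total_length - p$K) %/% p$k1 + 1L)
  if (is.null(bucket_bits))
    bucket_bits <- default_bucket_bits(n_slots, p$mode)
  stopifnot(bucket_bits >= 0, bucket_bits <= 30)
  idx <- cpp_build_index(R$text, p$k1, p$K, as.integer(bucket_bits))
  structure(list(bucket = idx$bucket, pos = idx$pos,
                 bucket_bits = as.integer(bucket_bits),
                 K = p$K, k1 = p$k1, n_stored = length(idx$pos)),
            class = "seed_index")
}

#' Look up candidate reference positions for a query K-mer
#'
#' Returns the contents of the k-mer's bucket; may contain false positives
#' (hash collisions) which callers must reject by textual comparison. A k-mer
#' containing a non-ACGT symbol yields an empty result.
#'
#' @param idx a [build_seed_index()] index.
#' @param kmer string of length `idx$K`.
#' @return Numeric vector of absolute 0-based reference positions.
#' @export
seed_lookup <- function(idx, kmer) {
  stopifnot(inherits(idx, "seed_index"), nchar(kmer) == idx$K)
  cpp_lookup(idx$bucket, idx$pos, kmer, idx$bucket_bits)
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> K=%d k1=%d bucket_bits=%d stored=%d\n",
              x$K, x$k1, x$bucket_bits, x$n_stored))
  invisible(x)
}
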