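#' Seed-and-extend MEM engine
#'
#' The query is probed at every k2-th position. Each candidate reference
#' position from the seed index is verified textually (hash collisions
#' rejected), extended maximally left and right under [chars_match()], and
#' kept if the run reaches the minimum length L. A diagonal containment
#' filter skips candidate seeds lying wholly inside a MEM already found on
#' the same diagonal — for near-identical genomes this removes almost all
#' redundant extensions, and it is lossless: a contained same-diagonal seed
#' would re-derive exactly the same MEM.
#'
#' @name mem_engine
NULL

#' Character match predicate
#'
#' True iff the two bytes are equal and unambiguous nucleotides (A/C/G/T).
#' N, other IUPAC codes and the separator byte never match, even themselves,
#' so no match extends across a sequence boundary or an ambiguity run.
#'
#' @param a,b single characters.
#' @return Logical.
#' @export
chars_match <- function(a, b) {
  a == b & a %in% c("A", "C", "G", "T")
}

#' Maximal extension of a verified seed
#'
#' @param R,Q `mem_genome` objects.
#' @param i,j absolute 0-based seed starts in R and Q; the K-mers at (i, j)
#'   must already be textually equal and all-ACGT.
#' @param K seed length.
#' @param L minimum MEM length; runs shorter than L yield `NULL`.
#' @return Numeric vector `c(rStart, qStart, length)` or `NULL`.
#' @export
extend_seed <- function(R, Q, i, j, K, L = 0) {
  t <- cpp_extend(R$text, Q$text, i, j, as.integer(K))
  if (t[3] < L) return(NULL)
  c(rStart = t[1], qStart = t[2], length = t[3])
}

#' Create an empty diagonal cache
#'
#' Holds, per diagonal d = rStart - qStart, the query interval of the most
#' recent MEM recorded on that diagonal. Used by [containment_skip()]. The
#' engine's compiled scan keeps an equivalent internal cache; this R-level
#' structure exposes the same contract for direct use and testing.
#'
#' @return An object of class `diagonal_cache`.
#' @export
diagonal_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(parent = emptyenv())
  class(e) <- "diagonal_cache"
  e
}

#' Record a MEM in a diagonal cache
#'
#' @param cache a [diagonal_cache()].
#' @param rStart,qStart,length the MEM triple (absolute 0-based).
#' @return The cache, invisibly.
#' @export
cache_record <- function(cache, rStart, qStart, length) {
  assign(as.character(rStart - qStart), c(qStart, qStart + length),
         envir = cache$map)
  invisible(cache)
}

#' Containment test for a candidate seed
#'
#' True iff the cache holds, on diagonal i - j, an interval `[qs, qe)` with
#' `qs <= j` and `j + K <= qe`: the seed lies wholly inside an already-found
#' MEM on the same diagonal, so extending it would reproduce that MEM.
#'
#' @param cache a [diagonal_cache()].
#' @param i,j candidate absolute starts in R and Q.
#' @param K seed length.
#' @return Logical.
#' @export
containment_skip <- function(cache, i, j, K) {
  iv <- get0(as.character(i - j), envir = cache$map)
  !is.null(iv) && iv[1] <= j && j + K <= iv[2]
}

#' Scan the query against a seed index
#'
#' Probes every query position j with `j %% k2 == 0` and a clean K-mer,
#' verifies candidates, extends, filters by L, and returns the emitted
#' triples. The multiset may contain duplicates (one MEM reached from several
#' seeds, or from overlapping worker chunks); the set of distinct triples
#' equals the set of all true MEMs of length >= L. With `workers > 1` the
#' sampled positions are split into contiguous chunks, each scanned with its
#' own containment cache; the distinct result is independent of the split.
#'
#' @param R,Q `mem_genome` objects.
#' @param idx a [build_seed_index()] built from `R` with the same params.
#' @param p a [mem_params()] object.
#' @param workers number of scan chunks (>= 1).
#' @param containment apply the diagonal containment filter (lossless).
#' @return A list with `triples` (matrix, columns rStart/qStart/length, in
#'   emission order, possibly duplicated), `chunk` (worker id per row) and
#'   counters `n_probed`, `n_candidates`, `n_verified`, `n_emitted`.
#' @export
scan_query <- function(R, Q, idx, p, workers = 1L, containment = TRUE) {
  stopifnot(inherits(idx, "seed_index"), inherits(p, "mem_params"))
  if (idx$K != p$K || idx$k1 != p$k1)
    stop("seed index was built with different parameters than supplied")
  nQ <- Q$total_length
  counters <- c(n_probed = 0, n_candidates = 0, n_verified = 0, n_emitted = 0)
  empty <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("rStart", "qStart", "length")))
  if (nQ < p$K)
    return(list(triples = empty, chunk = integer(0), n_chunks = 1L,
                counters = counters))
  # contiguous chunks over the sampled positions 0, k2, 2*k2, ...
  n_slots <- (nQ - p$K) %/% p$k2 + 1
  workers <- max(1L, as.integer(workers))
  bounds <- unique(round(seq(0, n_slots, length.out = workers + 1)))
  parts <- vector("list", length(bounds) - 1L)
  chunk <- integer(0)
  for (w in seq_len(length(bounds) - 1L)) {
    j_lo <- bounds[w] * p$k2
    j_hi <- if (w == length(bounds) - 1L) nQ else bounds[w + 1L] * p$k2
    res <- cpp_scan(R$text, Q$text, idx$bucket, idx$pos,
                    p$K, p$k2, p$L, idx$bucket_bits,
                    Q$records$start, j_lo, j_hi, containment)
    parts[[w]] <- res$triples
    chunk <- c(chunk, rep(w, nrow(res$triples)))
    counters <- counters + c(res$n_probed, res$n_candidates,
                             res$n_verified, res$n_emitted)
  }
  triples <- do.call(rbind, parts)
  colnames(triples) <- c("rStart", "qStart", "length")
  list(triples = triples, chunk = chunk, n_chunks = length(parts),
       counters = counters)
}

#' Distinct, sorted MEM triples
#'
#' Sorts a triple matrix by (qStart, rStart) and removes duplicate rows.
#'
#' @param triples matrix with columns rStart, qStart, length.
#' @return Sorted duplicate-free matrix of the same shape.
#' @export
mems_distinct <- function(triples) {
  if (nrow(triples) == 0) return(triples)
  s <- cpp_sort_triples(triples, 1024L, 0L)
  keep <- c(TRUE, rowSums(abs(s[-1, , drop = FALSE] -
                              s[-nrow(s), , drop = FALSE])) > 0)
  out <- s[keep, , drop = FALSE]
  colnames(out) <- c("rStart", "qStart", "length")
  out
}
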