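#' Synthetic genomes, mutated near-copies and a brute-force MEM oracle
#'
#' The generator emulates the regime the finder targets: multi-sequence
#' genomes and a query that is a mutated near-copy of the reference (point
#' substitutions, short indels, runs of N), as between two individuals or
#' assemblies of the same species. The oracle enumerates MEMs exactly by
#' walking every diagonal of the comparison grid.
#'
#' @name synthetic_oracle
NULL

#' Generate a random genome
#'
#' I.i.d. uniform A/C/G/T sequences; deterministic for a given seed.
#'
#' @param n_seqs number of sequences.
#' @param lengths integer vector (recycled to `n_seqs`) of sequence lengths.
#' @param seed RNG seed.
#' @param names sequence names.
#' @param path optional FASTA output path.
#' @return A [mem_genome()] (written to `path` as multi-FASTA if given).
#' @export
generate_genome <- function(n_seqs, lengths, seed,
                            names = sprintf("seq%d", seq_len(n_seqs)),
                            path = NULL) {
  stopifnot(n_seqs >= 1, all(lengths >= 1))
  lengths <- rep_len(as.integer(lengths), n_seqs)
  set.seed(seed)
  seqs <- vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  g <- mem_genome(seqs, names = names)
  if (!is.null(path)) write_fasta(g, path)
  g
}

#' Mutation model for near-copy simulation
#'
#' @param substitution_rate per-base probability of a point substitution.
#' @param insertion_rate per-base probability of starting an insertion.
#' @param deletion_rate per-base probability of starting a deletion.
#' @param max_indel_len maximum indel length, bases (lengths uniform in
#'   `1:max_indel_len`).
#' @param n_run_rate per-base probability of starting a run of N.
#' @param n_run_len length of each N run, bases.
#' @param seed RNG seed.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(substitution_rate = 0, insertion_rate = 0,
                           deletion_rate = 0, max_indel_len = 10L,
                           n_run_rate = 0, n_run_len = 5L, seed = 1L) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate, n_run_rate)
  stopifnot(all(rates >= 0), all(rates < 1), max_indel_len >= 1, n_run_len >= 1)
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 max_indel_len = as.integer(max_indel_len),
                 n_run_rate = n_run_rate, n_run_len = as.integer(n_run_len),
                 seed = as.integer(seed)),
            class = "mutation_model")
}

mutate_one <- function(s, m) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(x)
  bases <- c("A", "C", "G", "T")
  # substitutions: replace with a uniformly chosen different base
  hit <- which(stats::runif(n) < m$substitution_rate & x %in% bases)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- bases[(match(x[hit], bases) - 1L + shift) %% 4L + 1L]
  }
  # deletions: drop a run starting at each hit position
  if (m$deletion_rate > 0) {
    dstart <- which(stats::runif(n) < m$deletion_rate)
    if (length(dstart)) {
      dlen <- sample.int(m$max_indel_len, length(dstart), replace = TRUE)
      drop <- unique(unlist(mapply(function(s0, l) s0:min(s0 + l - 1L, n),
                                   dstart, dlen, SIMPLIFY = FALSE)))
      if (length(drop) < n) x <- x[-drop]
    }
  }
  # insertions: random bases inserted after each hit position
  if (m$insertion_rate > 0) {
    n2 <- length(x)
    istart <- which(stats::runif(n2) < m$insertion_rate)
    if (length(istart)) {
      ins <- lapply(sample.int(m$max_indel_len, length(istart), replace = TRUE),
                    function(l) sample(bases, l, replace = TRUE))
      pieces <- vector("list", 2L * length(istart) + 1L)
      prev <- 0L
      for (k in seq_along(istart)) {
        pieces[[2L * k - 1L]] <- x[seq_len(istart[k] - prev) + prev]
        pieces[[2L * k]] <- ins[[k]]
        prev <- istart[k]
      }
      pieces[[2L * length(istart) + 1L]] <-
        if (prev < n2) x[(prev + 1L):n2] else character(0)
      x <- unlist(pieces)
    }
  }
  # ambiguity runs
  if (m$n_run_rate > 0) {
    n3 <- length(x)
    nstart <- which(stats::runif(n3) < m$n_run_rate)
    for (s0 in nstart) x[s0:min(s0 + m$n_run_len - 1L, n3)] <- "N"
  }
  paste(x, collapse = "")
}

#' Apply a mutation model to every record of a genome
#'
#' Records are mutated independently; the record count is preserved and the
#' whole operation is deterministic for the model's seed.
#'
#' @param g a `mem_genome` with text.
#' @param m a [mutation_model()].
#' @return A mutated `mem_genome`.
#' @export
mutate_genome <- function(g, m) {
  stopifnot(inherits(g, "mem_genome"), inherits(m, "mutation_model"))
  set.seed(m$seed)
  seqs <- vapply(genome_sequences(g), mutate_one, character(1), m = m)
  mem_genome(seqs, names = g$records$name)
}

#' Brute-force MEM oracle by diagonal scanning
#'
#' Enumerates, on every diagonal of the (R, Q) grid, the maximal runs of
#' matching characters of length >= L. Exact and duplicate-free; cost is
#' `|R| * |Q|` character comparisons, guarded by `max_cells`.
#'
#' @param R,Q `mem_genome` objects.
#' @param L minimum MEM length.
#' @param max_cells guard on `|R| * |Q|`; exceeding it is an error (use a
#'   larger budget explicitly for big fixtures, or keep fixtures small).
#' @return Matrix with columns rStart, qStart, length, sorted by
#'   (qStart, rStart).
#' @export
oracle_mems <- function(R, Q, L, max_cells = 1e8) {
  stopifnot(inherits(R, "mem_genome"), inherits(Q, "mem_genome"))
  cells <- as.numeric(R$total_length) * as.numeric(Q$total_length)
  if (cells > max_cells)
    stop(sprintf(paste0("comparison grid has %.3g cells (> %.3g); raise ",
                        "max_cells explicitly or use smaller fixtures"),
                 cells, max_cells))
  m <- cpp_oracle_mems(R$text, Q$text, as.integer(L))
  mems_distinct(m)
}
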