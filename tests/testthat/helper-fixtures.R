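# shared fixture builders; everything is generated in code, no stored data

# reference genome + mutated near-copy, as in a same-species comparison
make_pair <- function(seq_len = 4500, n_seqs = 2, divergence = 0.01,
                      seed = 42) {
  r <- generate_genome(n_seqs, seq_len, seed = seed)
  m <- mutation_model(substitution_rate = divergence,
                      insertion_rate = divergence / 10,
                      deletion_rate = divergence / 10,
                      n_run_rate = divergence / 50,
                      seed = seed + 1000L)
  list(ref = r, query = mutate_genome(r, m))
}

# the worked-example genome: seven sequences starting at 0,4,7,13,17,27,32,
# chr2 spanning 4..6 (length 3, the shortest)
fig_genome <- function() {
  mem_genome_from_records(starts = c(0, 4, 7, 13, 17, 27, 32),
                          lengths = c(4, 3, 6, 4, 10, 5, 5),
                          names = paste0("chr", 1:7))
}

# independent in-memory reference pipeline: full sort + dedup + conversion,
# formatted exactly like the collator's file output
reference_output_lines <- function(R, Q, L) {
  tri <- oracle_mems(R, Q, L, max_cells = 2e8)
  rmap <- build_predecessor(R)
  qmap <- build_predecessor(Q)
  lines <- character(0)
  for (s in seq_len(nrow(Q$records))) {
    lines <- c(lines, paste0("> ", Q$records$name[s]))
    rows <- tri[locate_sequence(qmap, tri[, 2]) == s, , drop = FALSE]
    if (nrow(rows) > 0) {
      ri <- locate_sequence(rmap, rows[, 1])
      lines <- c(lines, sprintf(" %s\t%.0f\t%.0f\t%.0f",
                                rmap$records$name[ri],
                                rows[, 1] - rmap$records$start[ri] + 1,
                                rows[, 2] - Q$records$start[s] + 1,
                                rows[, 3]))
    }
  }
  lines
}

# random match triples for sorter tests
random_triples <- function(n, max_coord = 2^30, seed = 1) {
  set.seed(seed)
  cbind(rStart = floor(runif(n, 0, max_coord)),
        qStart = floor(runif(n, 0, max_coord)),
        length = floor(runif(n, 50, 5000)))
}

strip_names <- function(m) {
  dimnames(m) <- NULL
  m
}
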