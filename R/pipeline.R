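#' Find all maximal exact matches between two genomes
#'
#' Runs the full pipeline: parameter selection, seed-index construction over
#' the reference, coprime-sampled scan of the query with verification,
#' maximal extension and the diagonal containment filter, block-wise
#' collation with spill files, k-way merge with deduplication, and
#' conversion to sequence-relative coordinates. The reported set is exactly
#' the set of all MEMs of length >= L (guaranteed by the coprime-sampling
#' condition k1*k2 <= L - K + 1). Results are independent of `workers`,
#' `containment`, `match_block` and `mode`; those knobs trade speed for
#' memory only.
#'
#' @param ref,query `mem_genome` objects or paths to multi-FASTA files.
#' @param L minimum MEM length, bases (>= 37).
#' @param mode `"default"` or `"memory-frugal"` (smaller hash table and
#'   buffers, seed length capped; identical results).
#' @param seed_length optional explicit seed length K.
#' @param workers number of scan chunks.
#' @param containment apply the diagonal containment filter.
#' @param bucket_bits optional hash-table size override.
#' @param match_block collation buffer capacity (triples).
#' @param sort_threshold comparison-sort size threshold.
#' @param out optional output file path (MUMmer-family text format).
#' @param temp_dir directory for spill files.
#' @param keep_temp keep spill files after the run.
#' @param verbose log per-phase counts.
#' @return An object of class `mem_result`: `matches` (data.frame with
#'   `query`, `ref`, `ref_pos`, `q_pos`, `length`; positions 1-based,
#'   sequence-relative), `params`, `counters`, `rescues`, `out`.
#' @examples
#' r <- generate_genome(2, c(4000, 3000), seed = 1)
#' q <- mutate_genome(r, mutation_model(substitution_rate = 0.01, seed = 2))
#' res <- find_mems(r, q, L = 50)
#' res
#' head(res$matches)
#' @export
find_mems <- function(ref, query, L = 50L,
                      mode = c("default", "memory-frugal"),
                      seed_length = NULL, workers = 1L, containment = TRUE,
                      bucket_bits = NULL, match_block = 2^21,
                      sort_threshold = 1024L, out = NULL,
                      temp_dir = tempfile("memspill"), keep_temp = FALSE,
                      verbose = FALSE) {
  mode <- match.arg(mode)
  R <- if (inherits(ref, "mem_genome")) ref else load_fasta(ref)
  Q <- if (inherits(query, "mem_genome")) query else load_fasta(query)
  p <- mem_params(L, mode, seed_length = seed_length)
  if (mode == "memory-frugal")
    match_block <- max(8L, as.integer(match_block) %/% 4L)
  idx <- build_seed_index(R, p, bucket_bits = bucket_bits)
  if (verbose)
    message(sprintf("index: %d stored positions, %d bucket bits",
                    idx$n_stored, idx$bucket_bits))
  scan <- scan_query(R, Q, idx, p, workers = workers,
                     containment = containment)
  rmap <- build_predecessor(R)
  qmap <- build_predecessor(Q)
  cfg <- collator_config(match_block = match_block,
                         sort_threshold = sort_threshold,
                         temp_dir = temp_dir, workers = workers)
  if (!keep_temp) on.exit(unlink(cfg$temp_dir, recursive = TRUE), add = TRUE)

  nrec <- nrow(Q$records)
  n_workers <- scan$n_chunks
  qrec_of <- if (nrow(scan$triples) > 0)
    locate_sequence(qmap, scan$triples[, 2]) else integer(0)
  rescues <- 0L
  spill_files <- matrix(NA_character_, n_workers, nrec)
  for (w in seq_len(n_workers)) {
    st <- new_collator(cfg, worker = w)
    rows <- which(scan$chunk == w)
    recs <- qrec_of[rows]
    for (s in seq_len(nrec)) {
      collator_begin_sequence(st, s)
      for (i in rows[recs == s]) push_match(st, scan$triples[i, ])
      collator_end_sequence(st)
    }
    spill_files[w, ] <- st$files[as.character(seq_len(nrec))]
    rescues <- rescues + st$rescues
  }

  con <- if (!is.null(out)) file(out, open = "wt") else NULL
  if (!is.null(con)) on.exit(close(con), add = TRUE)
  per_seq <- vector("list", nrec)
  for (s in seq_len(nrec)) {
    merged <- merge_spills(spill_files[, s])
    recs <- convert_triples(merged, rmap, Q$records[s, ])
    if (!is.null(con)) write_output(con, Q$records$name[s], recs)
    if (nrow(recs) > 0)
      per_seq[[s]] <- cbind(query = Q$records$name[s], recs,
                            stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, per_seq)
  if (is.null(matches))
    matches <- data.frame(query = character(0), ref_name = character(0),
                          ref_pos = numeric(0), q_pos = numeric(0),
                          length = numeric(0), stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  counters <- c(scan$counters, n_mems = nrow(matches))
  if (verbose)
    message(sprintf(paste0("probed %.0f seeds, %.0f candidates, %.0f verified, ",
                           "%.0f emitted, %d distinct MEMs, %d rescue(s)"),
                    counters["n_probed"], counters["n_candidates"],
                    counters["n_verified"], counters["n_emitted"],
                    nrow(matches), rescues))
  structure(list(matches = matches, params = p, counters = counters,
                 rescues = rescues, out = out,
                 n_ref_seqs = nrow(R$records), n_query_seqs = nrec),
            class = "mem_result")
}

#' @export
print.mem_result <- function(x, ...) {
  cat(sprintf(paste0("<mem_result> %d MEM(s) of length >= %d ",
                     "(%d ref / %d query sequence(s); K=%d, k1=%d, k2=%d)\n"),
              nrow(x$matches), x$params$L, x$n_ref_seqs, x$n_query_seqs,
              x$params$K, x$params$k1, x$params$k2))
  if (!is.null(x$out)) cat(sprintf("  written to %s\n", x$out))
  invisible(x)
}

#' @method summary mem_result
#' @export
summary.mem_result <- function(object, ...) {
  m <- object$matches
  cat(sprintf("MEMs: %d  (L >= %d, mode %s)\n", nrow(m), object$params$L,
              object$params$mode))
  if (nrow(m) > 0) {
    cat(sprintf("length: min %.0f, median %.0f, max %.0f\n",
                min(m$length), stats::median(m$length), max(m$length)))
    tab <- table(m$query)
    for (q in names(tab)) cat(sprintf("  %s: %d MEM(s)\n", q, tab[[q]]))
  }
  cat(sprintf(paste0("seeds probed: %.0f; candidates: %.0f; verified: %.0f; ",
                     "emitted: %.0f; rescues: %d\n"),
              object$counters["n_probed"], object$counters["n_candidates"],
              object$counters["n_verified"], object$counters["n_emitted"],
              object$rescues))
  invisible(object)
}
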