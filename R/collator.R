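#' Match collation: block-wise sort, spill, rescue, merge, output
#'
#' Matches arrive nearly — but not exactly — in output order and may repeat.
#' Rather than holding a whole sequence's matches in memory, the collator
#' keeps a bounded buffer: when it fills, the buffer is sorted and its first
#' three quarters are spilled to a temporary file, the last quarter being
#' retained as overlap so that later arrivals still sort ahead of the next
#' spill. If an arrival nevertheless sorts before the last spilled key, a
#' rescue pass re-reads the sequence's spill, merges, re-sorts and respills.
#' Per-worker spill files are finally k-way merged with cross-file
#' deduplication and written as MUMmer-family text output.
#'
#' @name collator_output
NULL

#' Collator configuration
#'
#' @param match_block buffer capacity in triples (>= 8, divisible by 4).
#' @param sort_threshold below or at this size a comparison sort is used;
#'   above it the radix path.
#' @param dump_fraction fraction of a full block spilled per dump.
#' @param temp_dir directory for spill files.
#' @param workers intended worker count.
#' @return An object of class `collator_config`.
#' @export
collator_config <- function(match_block = 2^21, sort_threshold = 1024L,
                            dump_fraction = 3 / 4,
                            temp_dir = tempfile("memspill"), workers = 1L) {
  match_block <- as.integer(match_block)
  stopifnot(match_block >= 8L, match_block %% 4L == 0L,
            dump_fraction > 0, dump_fraction < 1, sort_threshold >= 1)
  structure(list(match_block = match_block,
                 sort_threshold = as.integer(sort_threshold),
                 dump_fraction = dump_fraction,
                 temp_dir = temp_dir, workers = as.integer(workers)),
            class = "collator_config")
}

#' Pack a match triple into a sort key
#'
#' Encodes (qStart, rStart) as a fixed-width lowercase-hex string whose
#' bytewise order equals the lexicographic order on the coordinate pair
#' (query position dominates, as required for the output ordering).
#'
#' @param triples matrix with columns rStart, qStart, length (or a single
#'   triple vector).
#' @param q_bits,r_bits key field widths in bits (multiples of 4, <= 52).
#' @return Character vector of keys.
#' @export
pack_key <- function(triples, q_bits = 40L, r_bits = 40L) {
  if (is.null(dim(triples))) triples <- matrix(triples, nrow = 1L)
  stopifnot(q_bits %% 4 == 0, r_bits %% 4 == 0, q_bits <= 52, r_bits <= 52)
  r <- triples[, 1]
  q <- triples[, 2]
  if (any(q >= 2^q_bits) || any(r >= 2^r_bits) || any(q < 0) || any(r < 0))
    stop(sprintf("coordinate exceeds the %d/%d-bit key widths", q_bits, r_bits))
  paste0(to_hex(q, q_bits %/% 4L), to_hex(r, r_bits %/% 4L))
}

# fixed-width lowercase hex for doubles up to 2^52, in 20-bit chunks
to_hex <- function(x, digits) {
  if (digits <= 5L) return(sprintf(paste0("%0", digits, "x"), as.integer(x)))
  hi <- x %/% 2^20
  lo <- x %% 2^20
  paste0(to_hex(hi, digits - 5L), sprintf("%05x", as.integer(lo)))
}

# lexicographic (qStart, rStart) comparison of two triples
key_lt <- function(a, b) {
  a[2] < b[2] || (a[2] == b[2] && a[1] < b[1])
}

#' Sort a block of match triples
#'
#' Ascending by (qStart, rStart). At or below the comparison threshold a
#' comparison sort is used; above it an LSD radix sort over the six
#' most-significant bytes of the packed 80-bit key followed by a comparison
#' finish within equal-prefix runs. Both paths produce identical results;
#' the radix-variant hardware selection heuristic is exposed only as this
#' single `method` knob.
#'
#' @param triples matrix with columns rStart, qStart, length.
#' @param cfg a [collator_config()].
#' @param method `"auto"` (threshold governs), `"comparison"`, or `"radix"`.
#' @return The sorted matrix.
#' @export
sort_block <- function(triples, cfg = collator_config(),
                       method = c("auto", "comparison", "radix")) {
  method <- match.arg(method)
  if (nrow(triples) <= 1L) return(triples)
  m <- cpp_sort_triples(triples, cfg$sort_threshold,
                        match(method, c("auto", "comparison", "radix")) - 1L)
  colnames(m) <- c("rStart", "qStart", "length")
  m
}

#' Create a collator for one worker
#'
#' @param cfg a [collator_config()].
#' @param worker worker id (used in spill-file names).
#' @return A stateful collator object (environment).
#' @export
new_collator <- function(cfg, worker = 1L) {
  dir.create(cfg$temp_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$worker <- as.integer(worker)
  st$seq_id <- NA_integer_
  st$files <- character(0)
  st$con <- NULL
  st$buf <- matrix(NA_real_, min(cfg$match_block, 4096L), 3L)
  st$n <- 0L
  st$last <- NULL
  st$rescues <- 0L
  st$dumps <- 0L
  class(st) <- "mem_collator"
  st
}

#' Begin collation for a query sequence
#'
#' @param st a [new_collator()] state.
#' @param seq_id 1-based index of the query sequence.
#' @return `st`, invisibly.
#' @export
collator_begin_sequence <- function(st, seq_id) {
  stopifnot(is.null(st$con))
  st$seq_id <- as.integer(seq_id)
  path <- file.path(st$cfg$temp_dir,
                    sprintf("spill_w%d_s%d.tsv", st$worker, st$seq_id))
  st$files[as.character(seq_id)] <- path
  st$con <- file(path, open = "wt")
  st$n <- 0L
  st$last <- NULL
  invisible(st)
}

#' Push one match triple into the collator
#'
#' @param st collator state (a sequence must be open).
#' @param t numeric triple `c(rStart, qStart, length)`.
#' @return `st`, invisibly.
#' @export
push_match <- function(st, t) {
  if (st$n == nrow(st$buf) && st$n < st$cfg$match_block) {
    grow <- matrix(NA_real_, min(2L * nrow(st$buf), st$cfg$match_block), 3L)
    grow[seq_len(st$n), ] <- st$buf[seq_len(st$n), ]
    st$buf <- grow
  }
  st$n <- st$n + 1L
  st$buf[st$n, ] <- t
  if (st$n == st$cfg$match_block) collator_dump(st)
  invisible(st)
}

# sort the full buffer, spill the first dump_fraction of it, retain the rest
collator_dump <- function(st) {
  sorted <- sort_block(st$buf[seq_len(st$n), , drop = FALSE], st$cfg)
  nd <- as.integer(st$cfg$dump_fraction * st$cfg$match_block)
  if (!is.null(st$last) && key_lt(sorted[1L, ], st$last)) {
    collator_rescue(st, sorted)
    return(invisible(st))
  }
  spill_rows(st, sorted[seq_len(nd), , drop = FALSE])
  st$dumps <- st$dumps + 1L
  nrest <- st$n - nd
  st$buf[seq_len(nrest), ] <- sorted[nd + seq_len(nrest), ]
  st$n <- nrest
  invisible(st)
}

# write sorted rows to the spill stream, skipping duplicates of the previous
# row or of the last spilled triple
spill_rows <- function(st, rows) {
  if (nrow(rows) == 0L) return(invisible(st))
  keep <- c(TRUE, rowSums(abs(rows[-1L, , drop = FALSE] -
                              rows[-nrow(rows), , drop = FALSE])) > 0)
  if (!is.null(st$last) && all(rows[1L, ] == st$last)) keep[1L] <- FALSE
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L) return(invisible(st))
  writeLines(sprintf("%.0f\t%.0f\t%.0f", rows[, 1], rows[, 2], rows[, 3]),
             st$con)
  st$last <- rows[nrow(rows), ]
  invisible(st)
}

#' Rescue pass after a spill order violation
#'
#' Re-reads everything spilled so far for the current sequence, merges it
#' with the in-memory triples, fully sorts and deduplicates, rewrites the
#' spill file, and retains the final quarter-block in memory as fresh
#' overlap. Slower and more memory-hungry than the normal path, but exact.
#'
#' @param st collator state.
#' @param current sorted in-memory triples at the moment of the violation.
#' @param final if TRUE (end of sequence) nothing is retained.
#' @return `st`, invisibly.
#' @export
collator_rescue <- function(st, current, final = FALSE) {
  st$rescues <- st$rescues + 1L
  warning(paste("match spill order violation; running the rescue merge.",
                "Consider a larger match_block."), call. = FALSE)
  close(st$con)
  prev <- read_spill(st$files[as.character(st$seq_id)])
  all_rows <- mems_distinct(rbind(prev, current))
  keep <- if (final) 0L else min(nrow(all_rows), st$cfg$match_block %/% 4L)
  nspill <- nrow(all_rows) - keep
  st$con <- file(st$files[as.character(st$seq_id)], open = "wt")  # truncate
  st$last <- NULL
  spill_rows(st, all_rows[seq_len(nspill), , drop = FALSE])
  if (keep > 0L) st$buf[seq_len(keep), ] <- all_rows[nspill + seq_len(keep), ]
  st$n <- keep
  invisible(st)
}

#' Finish collation for the current query sequence
#'
#' Sorts and spills the remaining buffer and closes the spill stream.
#'
#' @param st collator state.
#' @return `st`, invisibly.
#' @export
collator_end_sequence <- function(st) {
  if (st$n > 0L) {
    sorted <- sort_block(st$buf[seq_len(st$n), , drop = FALSE], st$cfg)
    if (!is.null(st$last) && key_lt(sorted[1L, ], st$last)) {
      collator_rescue(st, sorted, final = TRUE)
    } else {
      spill_rows(st, sorted)
    }
  }
  close(st$con)
  st$con <- NULL
  st$n <- 0L
  st$last <- NULL
  invisible(st)
}

read_spill <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    return(matrix(numeric(0), 0L, 3L))
  matrix(scan(path, what = numeric(), sep = "\t", quiet = TRUE),
         ncol = 3L, byrow = TRUE)
}

read_one_triple <- function(con) {
  ln <- readLines(con, n = 1L)
  if (length(ln) == 0L) return(NULL)
  as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]])
}

#' Streaming k-way merge of spill files
#'
#' Each input file must be internally sorted by (qStart, rStart); the merge
#' removes duplicates across files and returns the globally sorted stream.
#'
#' @param files spill-file paths (missing files are treated as empty).
#' @return Matrix with columns rStart, qStart, length.
#' @export
merge_spills <- function(files) {
  empty <- matrix(numeric(0), 0L, 3L,
                  dimnames = list(NULL, c("rStart", "qStart", "length")))
  files <- files[file.exists(files)]
  if (length(files) == 0L) return(empty)
  cons <- lapply(files, file, open = "rt")
  on.exit(for (con in cons) close(con), add = TRUE)
  nxt <- lapply(cons, read_one_triple)
  out <- vector("list", 256L)
  n_out <- 0L
  last <- NULL
  repeat {
    avail <- which(!vapply(nxt, is.null, logical(1)))
    if (length(avail) == 0L) break
    best <- avail[1L]
    for (k in avail[-1L]) if (key_lt(nxt[[k]], nxt[[best]])) best <- k
    t <- nxt[[best]]
    if (is.null(last) || any(t != last)) {
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- t
      last <- t
    }
    nxt[best] <- list(read_one_triple(cons[[best]]))  # keep slot on NULL
  }
  if (n_out == 0L) return(empty)
  m <- do.call(rbind, out[seq_len(n_out)])
  colnames(m) <- c("rStart", "qStart", "length")
  m
}

#' Convert an absolute match triple to a sequence-relative output record
#'
#' @param t triple `c(rStart, qStart, length)` (absolute 0-based).
#' @param rmap reference [build_predecessor()] map.
#' @param qrecord one-row data.frame: the query record containing `qStart`.
#' @return List with `ref_name`, `ref_pos` (1-based), `q_pos` (1-based),
#'   `length`.
#' @export
to_output_record <- function(t, rmap, qrecord) {
  ri <- locate_sequence(rmap, t[1])
  rec <- rmap$records[ri, ]
  if (t[1] < rec$start || t[1] >= rec$start + rec$length)
    stop("internal error: match start maps outside its reference record")
  list(ref_name = rec$name, ref_pos = t[1] - rec$start + 1,
       q_pos = t[2] - qrecord$start + 1, length = t[3])
}

# vectorized conversion of a sorted triple matrix for one query record
convert_triples <- function(triples, rmap, qrecord) {
  if (nrow(triples) == 0L)
    return(data.frame(ref_name = character(0), ref_pos = numeric(0),
                      q_pos = numeric(0), length = numeric(0)))
  ri <- locate_sequence(rmap, triples[, 1])
  data.frame(ref_name = rmap$records$name[ri],
             ref_pos = triples[, 1] - rmap$records$start[ri] + 1,
             q_pos = triples[, 2] - qrecord$start + 1,
             length = triples[, 3],
             stringsAsFactors = FALSE)
}

#' Write final output for one query sequence
#'
#' Format (MUMmer/E-MEM family): a header line `> <query name>` followed by
#' one line per MEM, `" <refName>\t<refPos>\t<qPos>\t<length>"` with 1-based
#' positions. The header is emitted even when the sequence has no MEMs.
#'
#' @param con an open writable connection.
#' @param qname query sequence name.
#' @param records data.frame from [convert_triples()] / [to_output_record()].
#' @return Invisibly, the number of match lines written.
#' @export
write_output <- function(con, qname, records) {
  writeLines(paste0("> ", qname), con)
  if (nrow(records) > 0L)
    writeLines(sprintf(" %s\t%.0f\t%.0f\t%.0f", records$ref_name,
                       records$ref_pos, records$q_pos, records$length), con)
  invisible(nrow(records))
}
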