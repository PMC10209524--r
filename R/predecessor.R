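#' Constant-time predecessor structure for coordinate conversion
#'
#' Match positions are absolute over the concatenated genome, but output is
#' relative to the containing sequence. Finding the containing sequence is a
#' predecessor query: the rightmost record start <= position. Instead of a
#' binary search per query, the genome is sampled at regular steps no larger
#' than the shortest sequence, storing for each sampled position the record
#' containing it in array `Beg` of length ceiling((|G| + 0.5) / step). Because
#' the step never exceeds the shortest sequence length, at most one record
#' boundary falls inside any cell, so a query inspects `Beg[floor(pos/step)]`
#' and at most its successor.
#'
#' @name predecessor_map
NULL

#' Power-of-two effective sampling step
#'
#' To replace divisions by shifts, the computed step (the shortest sequence
#' length) is rounded down to the largest power of two not greater than it.
#'
#' @param lmin length of the shortest sequence (>= 1).
#' @return The largest power of two <= `lmin`.
#' @export
effective_step <- function(lmin) {
  if (lmin < 1) stop("lmin must be >= 1 (zero-length records are dropped upstream)")
  2^floor(log2(lmin))
}

#' Build the sampled predecessor map
#'
#' @param g a `mem_genome` (text optional; records and total length suffice).
#' @param step sampling step in bases; default [effective_step()] of the
#'   shortest record length. Must satisfy `1 <= step <= min_record_length(g)`.
#' @param max_cells guard: if `Beg` would exceed this many cells the map
#'   falls back to binary search (with a warning); correctness is unaffected.
#' @return An object of class `predecessor_map` with fields `step`, `shift`
#'   (log2(step) if a power of two, else NA), `Beg` (1-based record indices),
#'   `records`, `total_length`, `fallback`.
#' @export
build_predecessor <- function(g, step = NULL, max_cells = 2^27) {
  stopifnot(inherits(g, "mem_genome"))
  lmin <- min_record_length(g)
  if (is.null(step)) step <- effective_step(lmin)
  if (step < 1 || step > lmin)
    stop(sprintf("step = %s must lie in [1, %s] (shortest sequence length)",
                 format(step), format(lmin)))
  n_cells <- ceiling((g$total_length + 0.5) / step)
  fallback <- n_cells > max_cells
  if (fallback) {
    warning(sprintf(paste0("predecessor map would need %.0f cells ",
                           "(> %.0f); falling back to binary search"),
                    n_cells, max_cells), call. = FALSE)
    Beg <- integer(0)
  } else {
    # Beg[c] = last record with start <= c*step (1-based record index)
    Beg <- findInterval((seq_len(n_cells) - 1) * step, g$records$start)
  }
  lg <- log2(step)
  m <- list(step = step,
            shift = if (lg == floor(lg)) as.integer(lg) else NA_integer_,
            Beg = Beg,
            records = g$records,
            total_length = g$total_length,
            fallback = fallback)
  class(m) <- "predecessor_map"
  m
}

#' Locate the sequence containing an absolute position
#'
#' Reads `Beg[floor(pos/step)]` and checks at most one successor record;
#' because the step is bounded by the shortest sequence length this is
#' sufficient, and the result equals a binary search over record starts.
#' Vectorized over `pos`.
#'
#' @param m a [build_predecessor()] map.
#' @param pos absolute 0-based position(s) inside some record (not on a
#'   separator byte).
#' @return Integer vector of 1-based record indices into `m$records`.
#' @export
locate_sequence <- function(m, pos) {
  stopifnot(inherits(m, "predecessor_map"))
  if (any(pos < 0 | pos >= m$total_length))
    stop("position out of range")
  if (m$fallback)
    return(findInterval(pos, m$records$start))
  cell <- if (!is.na(m$shift) && m$shift < 31L) pos %/% bitwShiftL(1L, m$shift)
          else pos %/% m$step
  a <- m$Beg[cell + 1]
  nxt <- a + 1L
  starts <- m$records$start
  bump <- nxt <= nrow(m$records) & pos >= starts[pmin(nxt, nrow(m$records))]
  ifelse(bump, nxt, a)
}

#' @export
print.predecessor_map <- function(x, ...) {
  cat(sprintf("<predecessor_map> step=%.0f cells=%d records=%d%s\n",
              x$step, length(x$Beg), nrow(x$records),
              if (x$fallback) " (binary-search fallback)" else ""))
  invisible(x)
}
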