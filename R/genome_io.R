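#' Genome containers and multi-FASTA input
#'
#' A genome is held as one concatenated uppercase text plus a table of
#' sequence records with absolute 0-based start offsets. Consecutive
#' sequences are separated by a single non-nucleotide byte (`">"`), which can
#' never take part in a match, so no maximal exact match spans two sequences.
#'
#' @name genome_io
NULL

MEM_SEPARATOR <- ">"

#' Construct a genome from named sequences
#'
#' Sequences are uppercased and concatenated in order with exactly one
#' separator byte between consecutive sequences (none before the first, none
#' after the last). Zero-length sequences are dropped with a warning.
#'
#' @param seqs character vector of sequences (any case).
#' @param names sequence names; defaults to `names(seqs)`.
#' @return An object of class `mem_genome`: a list with `text` (single
#'   uppercase string), `records` (data.frame with `name`, `start`, `length`),
#'   and `total_length`.
#' @export
mem_genome <- function(seqs, names = base::names(seqs)) {
  if (length(seqs) == 0L) stop("a genome needs at least one sequence")
  if (is.null(names)) names <- sprintf("seq%d", seq_along(seqs))
  lens <- nchar(seqs)
  if (any(lens == 0L)) {
    warning(sprintf("dropping %d zero-length sequence(s)", sum(lens == 0L)),
            call. = FALSE)
    names <- names[lens > 0L]
    seqs <- seqs[lens > 0L]
    lens <- lens[lens > 0L]
  }
  if (length(seqs) == 0L) stop("no sequences with length >= 1")
  if (anyDuplicated(names))
    warning("duplicate sequence names; kept verbatim", call. = FALSE)
  seqs <- toupper(unname(seqs))
  lens <- unname(lens)
  # start_{i+1} = start_i + len_i + 1 (one separator byte between records)
  starts <- cumsum(c(0, head(lens, -1L) + 1L))
  text <- paste(seqs, collapse = MEM_SEPARATOR)
  g <- list(
    text = text,
    records = data.frame(name = as.character(names), start = starts,
                         length = as.integer(lens),
                         stringsAsFactors = FALSE),
    total_length = nchar(text)
  )
  class(g) <- "mem_genome"
  g
}

#' Build a genome object from an explicit records table
#'
#' Used where only coordinates matter (e.g. predecessor-map construction from
#' a published worked example); no separator-gap layout is imposed.
#'
#' @param starts absolute 0-based record starts, strictly increasing.
#' @param lengths record lengths (all >= 1).
#' @param names record names.
#' @param total_length total genome length; default covers the last record.
#' @return A `mem_genome` with `text = NULL`.
#' @export
mem_genome_from_records <- function(starts, lengths,
                                    names = sprintf("seq%d", seq_along(starts)),
                                    total_length = max(starts + lengths)) {
  stopifnot(length(starts) == length(lengths), all(lengths >= 1),
            !is.unsorted(starts, strictly = TRUE))
  g <- list(
    text = NULL,
    records = data.frame(name = as.character(names),
                         start = as.numeric(starts),
                         length = as.numeric(lengths),
                         stringsAsFactors = FALSE),
    total_length = total_length
  )
  class(g) <- "mem_genome"
  g
}

#' Read a multi-FASTA file into a genome
#'
#' Headers are tokenized at the first whitespace. Line wrapping and CRLF line
#' endings are tolerated. Lowercase (soft-masked) input is uppercased and not
#' treated specially. Non-ACGT IUPAC codes are retained but can never
#' participate in a match.
#'
#' @param path path to a FASTA file.
#' @return A [mem_genome()] object.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e)
                    stop(sprintf("not a readable FASTA file (%s): %s",
                                 path, conditionMessage(e)), call. = FALSE))
  if (length(dss) == 0L)
    stop(sprintf("no sequences found in %s", path))
  nm <- sub("\\s.*$", "", names(dss))
  mem_genome(as.character(dss), names = nm)
}

#' Extract the per-record sequences from a genome
#'
#' @param g a `mem_genome` with text.
#' @return Named character vector of uppercase sequences.
#' @export
genome_sequences <- function(g) {
  stopifnot(inherits(g, "mem_genome"), !is.null(g$text))
  out <- substring(g$text, g$records$start + 1,
                   g$records$start + g$records$length)
  names(out) <- g$records$name
  out
}

#' Write a genome to a multi-FASTA file
#'
#' @param g a `mem_genome` with text.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  seqs <- genome_sequences(g)
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, filepath = path, width = width)
  invisible(path)
}

#' Length of the shortest sequence in a genome
#'
#' The shortest reference sequence bounds the sampling step of the
#' predecessor structure.
#'
#' @param g a `mem_genome`.
#' @return Minimum record length, in bases.
#' @export
min_record_length <- function(g) {
  stopifnot(inherits(g, "mem_genome"), nrow(g$records) >= 1L)
  min(g$records$length)
}

#' @export
print.mem_genome <- function(x, ...) {
  cat(sprintf("<mem_genome> %d sequence(s), %s bases total (incl. separators)\n",
              nrow(x$records), format(x$total_length, big.mark = ",")))
  n <- min(nrow(x$records), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %s  start=%.0f  length=%.0f\n", x$records$name[i],
                x$records$start[i], x$records$length[i]))
  if (nrow(x$records) > n) cat(sprintf("  ... %d more\n", nrow(x$records) - n))
  invisible(x)
}
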