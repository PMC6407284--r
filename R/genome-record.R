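#' Create a genome record
#'
#' A `genome_record` holds a single named nucleotide sequence together with
#' its GC percentage, which the scanner uses as the reference scale for the
#' "GC-rich stem" criterion of hairpin pause sites.
#'
#' The sequence is normalised on construction: letters are uppercased, `U`
#' is mapped to `T` (RNA input), and any character outside `{A,C,G,T,N}` is
#' replaced by `N` with a warning.  `N` counts as neither C nor G in ratio
#' computations, never pairs in hairpin stems and never matches the pause
#' consensus element.
#'
#' @param id Short text label for the sequence.
#' @param sequence Nucleotide string (length >= 1).
#' @return An object of class `genome_record` with fields `id`, `sequence`
#'   and `gc_percent` (computed over unambiguous bases only).
#' @examples
#' rec <- genome_record("toy", "ACGTACGT")
#' rec$gc_percent  # 50
#' @export
genome_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) < 1L) {
    stop("sequence must contain at least one base", call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, gc_percent = gc_percent(sequence)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d nt, GC%% = %.2f\n",
              x$id, nchar(x$sequence), x$gc_percent))
  invisible(x)
}

#' Normalise a nucleotide string
#'
#' Uppercases, maps U to T, and replaces characters outside `{A,C,G,T,N}`
#' by `N` (with a warning).
#'
#' @param sequence Nucleotide string.
#' @return Normalised string over the alphabet `{A,C,G,T,N}`.
#' @export
normalize_sequence <- function(sequence) {
  s <- chartr("u", "t", toupper(sequence))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGTN]", s)) {
    warning("characters outside {A,C,G,T,N} replaced by N", call. = FALSE)
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

#' GC percentage of a sequence
#'
#' Computed as 100*(#G + #C) / (#A + #C + #G + #T); ambiguous bases are
#' excluded from the denominator.
#'
#' @param sequence Nucleotide string.
#' @return Percentage in `[0, 100]` (NaN for an all-N sequence).
#' @export
gc_percent <- function(sequence) {
  ch <- seq_chars(sequence)
  gc <- sum(ch == "G" | ch == "C")
  acgt <- sum(ch == "A" | ch == "C" | ch == "G" | ch == "T")
  100 * gc / acgt
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}`.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

## split into a character vector of single bases
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1L]]
}

## accept either a genome_record or a plain string
as_sequence <- function(x) {
  if (inherits(x, "genome_record")) x$sequence
  else if (is.character(x) && length(x) == 1L) normalize_sequence(x)
  else stop("expected a genome_record or a single nucleotide string",
            call. = FALSE)
}
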