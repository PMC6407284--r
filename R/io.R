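## File formats.  FASTA via Biostrings; wiggle/bedGraph/BED/GFF3 via
## rtracklayer.  All R-side coordinates are 1-based inclusive; BED output
## follows the standard 0-based half-open convention (handled by
## rtracklayer on export).

#' Read genome records from a FASTA file
#'
#' Sequences are normalised on load (see [normalize_sequence()]) and each
#' record's GC percentage is computed.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A list of [genome_record()] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]))
  })
}

#' Write genome records to a FASTA file
#'
#' @param records A [genome_record()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## expand a scored GRanges-like track into per-base vectors per record
expand_track <- function(gr, records) {
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1L))
  names(lens) <- vapply(records, `[[`, "", "id")
  out <- lapply(lens, numeric)
  df <- data.frame(id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   score = GenomicRanges::mcols(gr)$score)
  for (i in seq_len(nrow(df))) {
    id <- df$id[i]
    if (!id %in% names(out)) next
    if (df$end[i] > lens[[id]] || df$start[i] < 1L) {
      stop(sprintf("coverage interval [%d, %d] outside record %s (length %d)",
                   df$start[i], df$end[i], id, lens[[id]]), call. = FALSE)
    }
    out[[id]][df$start[i]:df$end[i]] <- df$score[i]
  }
  out
}

#' Read per-base coverage tracks
#'
#' Accepts wiggle (fixedStep/variableStep) or bedGraph files; the format
#' is inferred from the file extension unless `format` is given.  Values
#' are expanded to per-base vectors on forward coordinates, with absent
#' positions defaulting to 0.  Strand-specific coverage is supplied as a
#' pair of files named `plus` and `minus`.
#'
#' @param path A single path, or a length-2 named vector
#'   `c(plus = ..., minus = ...)` for strand-specific tracks.
#' @param records The [genome_record()] list the track belongs to (used
#'   for lengths and bounds checking).
#' @param format Optional explicit format passed to
#'   [rtracklayer::import()] (e.g. `"wig"`, `"bedGraph"`).
#' @return A named list (one element per record id).  Each element is a
#'   per-base numeric vector, or, for strand-specific input, a list with
#'   components `plus` and `minus`.
#' @export
read_coverage <- function(path, records, format = NULL) {
  if (inherits(records, "genome_record")) records <- list(records)
  read_one <- function(p) {
    gr <- if (is.null(format)) rtracklayer::import(p)
          else rtracklayer::import(p, format = format)
    expand_track(gr, records)
  }
  if (length(path) == 2L && all(c("plus", "minus") %in% names(path))) {
    plus <- read_one(path[["plus"]])
    minus <- read_one(path[["minus"]])
    out <- lapply(names(plus), function(id) {
      list(plus = plus[[id]], minus = minus[[id]])
    })
    names(out) <- names(plus)
    out
  } else if (length(path) == 1L) {
    read_one(path)
  } else {
    stop("path must be one file or c(plus = ..., minus = ...)", call. = FALSE)
  }
}

#' Write a per-base coverage track as fixedStep wiggle
#'
#' @param values Per-base numeric vector (position 1 onwards).
#' @param record_id Record the track belongs to.
#' @param path Output path (conventionally `.wig`).
#' @return `path`, invisibly.
#' @export
write_wig <- function(values, record_id, path) {
  gr <- GenomicRanges::GRanges(
    record_id,
    IRanges::IRanges(seq_along(values), width = 1L),
    score = as.numeric(values))
  rtracklayer::export(gr, path, format = "wig")
  invisible(path)
}

#' Read intervals from a BED file
#'
#' @param path Path to a BED3+ file (track/browser header lines are
#'   skipped by the parser).
#' @return A data frame with columns `record_id`, `start`, `end` (1-based
#'   inclusive), `strand` (`"+"`, `"-"`, or `"*"` meaning both) and, when
#'   present, `name` and `score`.
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(record_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  mc <- GenomicRanges::mcols(gr)
  if (!is.null(mc$name)) df$name <- mc$name
  if (!is.null(mc$score)) df$score <- mc$score
  df
}

#' Read coding-sequence annotation
#'
#' Accepts either GFF3 (features of type `CDS` are kept) or a simple
#' 4-column tab-separated table `record_id, start, end, strand` with
#' 1-based inclusive coordinates.
#'
#' @param path Path to a `.gff`/`.gff3` file or a TSV.
#' @return Data frame with columns `record_id`, `start`, `end`, `strand`,
#'   `feature_kind`, sorted by record then start.
#' @export
read_cds <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type == "CDS"]
    df <- data.frame(record_id = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     feature_kind = "CDS", stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("CDS table needs 4 columns: id, start, end, strand",
                            call. = FALSE)
    df <- data.frame(record_id = as.character(df[[1L]]),
                     start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                     strand = as.character(df[[4L]]), feature_kind = "CDS",
                     stringsAsFactors = FALSE)
  }
  if (any(df$start > df$end)) stop("CDS with start > end", call. = FALSE)
  df <- df[order(df$record_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write prediction tables
#'
#' Always writes `<prefix>.tsv` (1-based inclusive coordinates, C/G ratio
#' to 3 decimals); optionally BED6 (`<prefix>.bed`, 0-based half-open,
#' score column = prediction score x 100 truncated to 0--1000) and GFF3
#' (`<prefix>.gff3`, feature type `terminator`).  Rows are sorted by
#' record then start.
#'
#' @param predictions A `rhoterm_predictions` data frame.
#' @param prefix Output path prefix.
#' @param formats Subset of `c("tsv", "bed", "gff3")`.
#' @param explain_scores If `TRUE`, the TSV additionally carries the
#'   per-bonus score breakdown columns.
#' @return Named character vector of the files written, invisibly.
#' @export
write_predictions <- function(predictions, prefix,
                              formats = c("tsv", "bed", "gff3"),
                              explain_scores = FALSE) {
  formats <- match.arg(formats, several.ok = TRUE)
  df <- as.data.frame(predictions)
  df <- df[order(df$record_id, df$rut_start), , drop = FALSE]
  ids <- if (nrow(df)) sprintf("RDT%04d", seq_len(nrow(df))) else character(0)
  written <- character(0)
  if ("tsv" %in% formats) {
    cols <- c("record_id", "strand", "rut_start", "rut_end", "cg_ratio",
              "pause_type", "pause_start", "pause_end", "score")
    if (explain_scores) {
      cols <- c(cols, "cg_bonus", "stem_gc_bonus", "loop_bonus",
                "stem_len_bonus", "consensus_bonus")
    }
    tsv <- df[, cols, drop = FALSE]
    tsv$cg_ratio <- sprintf("%.3f", df$cg_ratio)
    path <- paste0(prefix, ".tsv")
    write.table(tsv, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written["tsv"] <- path
  }
  if (nrow(df)) {
    span_start <- pmin(df$rut_start, df$pause_start)
    span_end <- pmax(df$rut_end, df$pause_end)
    gr <- GenomicRanges::GRanges(
      df$record_id, IRanges::IRanges(span_start, span_end),
      strand = df$strand)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  if ("bed" %in% formats) {
    bed <- gr
    if (length(bed)) {
      bed$name <- ids
      bed$score <- pmin(1000L, as.integer(floor(df$score * 100)))
    }
    path <- paste0(prefix, ".bed")
    rtracklayer::export(bed, path, format = "BED")
    written["bed"] <- path
  }
  if ("gff3" %in% formats) {
    gff <- gr
    if (length(gff)) {
      gff$source <- "rhoterm"
      gff$type <- "terminator"
      gff$score <- df$score
      gff$ID <- ids
    }
    path <- paste0(prefix, ".gff3")
    rtracklayer::export(gff, path, format = "GFF3")
    written["gff3"] <- path
  }
  invisible(written)
}
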