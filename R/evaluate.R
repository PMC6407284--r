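## Evaluation protocol: positive/negative set construction, balanced
## repeated subsampling with the five classification metrics, coverage
## gradient validation, and inter-predictor overlap counting.

#' Classification metrics from confusion counts
#'
#' Precision, recall (sensitivity), specificity and accuracy as
#' percentages, and the F1 score (harmonic mean of precision and recall)
#' on the fractional scale.  Undefined terms (zero denominators) are
#' returned as `NA`, never as 0.
#'
#' @param tp,fn,fp,tn Confusion counts (may be fractional means over
#'   repeats).
#' @return A list with `tp`, `fn`, `fp`, `tn`, `precision`, `recall`,
#'   `specificity`, `accuracy` (percent) and `f1` (in `[0, 1]`).
#' @examples
#' m <- metrics_from_counts(tp = 128, fn = 67, fp = 46, tn = 149)
#' round(c(m$precision, m$recall, m$specificity, m$accuracy), 1)
#' @export
metrics_from_counts <- function(tp, fn, fp, tn) {
  div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       precision = 100 * precision,
       recall = 100 * recall,
       specificity = 100 * div(tn, tn + fp),
       accuracy = 100 * div(tp + tn, tp + tn + fp + fn),
       f1 = f1)
}

#' Extract the positive sequence set upstream of terminator regions
#'
#' For each stranded region (e.g. a transcript whose extension marks a
#' Rho-dependent terminator just upstream), extracts the 300-nt sequence
#' immediately upstream in the region's own orientation: for `+` regions
#' the 300 nt before the region start; for `-` regions the reverse
#' complement of the 300 nt after the region end.  Regions without 300 nt
#' of genomic context are skipped with a warning.
#'
#' @param record A [genome_record()].
#' @param regions Data frame with columns `start`, `end` (1-based
#'   inclusive) and `strand` (`"+"`/`"-"`).
#' @param width Extracted length (default 300 nt).
#' @return Data frame with columns `start`, `end`, `strand`, `sequence`
#'   (coordinates of the extracted window on the forward strand).
#' @export
build_positive_set <- function(record, regions, width = 300L) {
  s <- record$sequence
  n <- nchar(s)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(regions))) {
    st <- regions$strand[i]
    if (st == "+") {
      a <- regions$start[i] - width
      b <- regions$start[i] - 1L
      if (a < 1L) { skipped <- skipped + 1L; next }
      seq_i <- substr(s, a, b)
    } else {
      a <- regions$end[i] + 1L
      b <- regions$end[i] + width
      if (b > n) { skipped <- skipped + 1L; next }
      seq_i <- revcomp(substr(s, a, b))
    }
    rows[[length(rows) + 1L]] <- data.frame(start = a, end = b, strand = st,
                                            sequence = seq_i)
  }
  if (skipped > 0L) {
    warning(sprintf("%d region(s) skipped: insufficient upstream context",
                    skipped), call. = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), sequence = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the negative sequence set from divergent intergenic regions
#'
#' Emits the gap between each pair of adjacent coding sequences where the
#' left CDS is on the minus strand and the right on the plus strand
#' (head-to-head divergence, so neither gene transcribes into the gap and
#' no terminator is expected there), provided the gap length is within
#' `min_len`--`max_len` nt.
#'
#' @param record A [genome_record()].
#' @param cds Data frame of CDS annotations (`record_id`, `start`, `end`,
#'   `strand`), e.g. from [read_cds()]; will be sorted by start.
#' @param min_len,max_len Inclusive gap-length bounds (defaults 200 and
#'   300 nt).
#' @return Data frame with columns `start`, `end`, `length`, `sequence`.
#' @export
build_negative_set <- function(record, cds, min_len = 200L, max_len = 300L) {
  cds <- cds[is.null(cds$record_id) | cds$record_id == record$id, ,
             drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  rows <- list()
  if (nrow(cds) >= 2L) {
    for (i in seq_len(nrow(cds) - 1L)) {
      left <- cds[i, ]
      right <- cds[i + 1L, ]
      if (left$strand != "-" || right$strand != "+") next
      a <- left$end + 1L
      b <- right$start - 1L
      len <- b - a + 1L
      if (len < min_len || len > max_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = a, end = b, length = len,
        sequence = substr(record$sequence, a, b))
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), sequence = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a terminator-presence predictor from the scanner
#'
#' Returns a function mapping a nucleotide string to its prediction table,
#' for use with [evaluate_balanced()].
#'
#' @param genome_gc Whole-genome GC percentage used as the hairpin
#'   GC-rich reference; if `NULL`, each sequence's own GC is used.
#' @param strand Strand(s) to scan (default both).
#' @param spacing_band See [rut_seed_scan()].
#' @return A function of one sequence string.
#' @export
make_scan_predictor <- function(genome_gc = NULL, strand = "both",
                                spacing_band = FALSE) {
  force(genome_gc); force(strand); force(spacing_band)
  function(sequence) {
    rec <- genome_record("query", sequence)
    if (!is.null(genome_gc)) rec$gc_percent <- genome_gc
    scan_genome(rec, strand = strand, spacing_band = spacing_band)
  }
}

#' Balanced repeated evaluation of a predictor
#'
#' Per repeat, the larger of the two sets is subsampled without
#' replacement to the smaller set's size.  A positive sequence with at
#' least one prediction counts exactly one true positive (never more),
#' otherwise one false negative; a negative sequence with at least one
#' prediction counts one false positive, otherwise one true negative.
#' Metrics are computed per repeat and then averaged; mean counts are
#' reported alongside.
#'
#' @param positives,negatives Character vectors of sequences (or data
#'   frames with a `sequence` column).
#' @param predictor Function mapping a sequence to a prediction table (or
#'   a count); see [make_scan_predictor()].
#' @param n_repeats Number of random subsampling repeats (default 10).
#' @param seed Integer seed making the subsampling reproducible.
#' @return An object of class `evaluation_report`: mean `counts`, mean
#'   `precision`, `recall`, `specificity`, `accuracy` (percent), `f1`,
#'   the per-repeat table, `n_repeats` and `seed`.
#' @export
evaluate_balanced <- function(positives, negatives, predictor,
                              n_repeats = 10L, seed = 1L) {
  get_seqs <- function(x) {
    if (is.data.frame(x)) as.character(x$sequence) else as.character(x)
  }
  positives <- get_seqs(positives)
  negatives <- get_seqs(negatives)
  if (!length(positives) || !length(negatives)) {
    stop("both sequence sets must be non-empty", call. = FALSE)
  }
  n_pred <- function(seqs, label) {
    vapply(seq_along(seqs), function(i) {
      res <- tryCatch(predictor(seqs[i]), error = function(e) {
        stop(sprintf("predictor failed on %s sequence %d: %s",
                     label, i, conditionMessage(e)), call. = FALSE)
      })
      k <- if (is.data.frame(res)) nrow(res) else as.integer(res)
      k > 0L
    }, logical(1L))
  }
  # predictions are deterministic: compute once per unique sequence
  pos_hit <- n_pred(positives, "positive")
  neg_hit <- n_pred(negatives, "negative")
  m <- min(length(positives), length(negatives))
  set.seed(seed)
  reps <- lapply(seq_len(n_repeats), function(r) {
    pi <- if (length(positives) > m) sample(length(positives), m)
          else seq_along(positives)
    ni <- if (length(negatives) > m) sample(length(negatives), m)
          else seq_along(negatives)
    tp <- sum(pos_hit[pi]); fn <- m - tp
    fp <- sum(neg_hit[ni]); tn <- m - fp
    mt <- metrics_from_counts(tp, fn, fp, tn)
    data.frame(repeat_ = r, tp = tp, fn = fn, fp = fp, tn = tn,
               precision = mt$precision, recall = mt$recall,
               specificity = mt$specificity, accuracy = mt$accuracy,
               f1 = mt$f1)
  })
  per_repeat <- do.call(rbind, reps)
  structure(list(
    counts = list(tp = mean(per_repeat$tp), fn = mean(per_repeat$fn),
                  fp = mean(per_repeat$fp), tn = mean(per_repeat$tn)),
    precision = mean(per_repeat$precision),
    recall = mean(per_repeat$recall),
    specificity = mean(per_repeat$specificity),
    accuracy = mean(per_repeat$accuracy),
    f1 = mean(per_repeat$f1),
    per_repeat = per_repeat,
    n_repeats = n_repeats, seed = seed
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d repeat(s), seed %d\n",
              x$n_repeats, x$seed))
  cat(sprintf("  mean counts: TP %.1f, FN %.1f, FP %.1f, TN %.1f\n",
              x$counts$tp, x$counts$fn, x$counts$fp, x$counts$tn))
  cat(sprintf(paste0("  precision %.1f%%  recall %.1f%%  specificity %.1f%%",
                     "  accuracy %.1f%%  F1 %.2f\n"),
              x$precision, x$recall, x$specificity, x$accuracy, x$f1))
  invisible(x)
}

## coverage value lookup handling strand-specific tracks
track_values <- function(track, strand) {
  if (is.list(track) && !is.null(track$plus)) {
    if (strand == "+") track$plus else track$minus
  } else {
    track
  }
}

#' Validate predictions against an RNA-seq coverage gradient
#'
#' A prediction is "next to an expressed region" when the coverage at the
#' RUT 5'-end point is at least `min_reads` (default 10).  Among those, it
#' is validated when the ratio of that upstream value to the coverage 150
#' nt downstream of the RUT 3'-end point (i.e. past the pause site) is at
#' least `min_drop` (default 1.5); a zero downstream value gives a ratio
#' of `Inf` (the strongest possible gradient) and validates.  Predictions
#' whose downstream point falls outside the record are excluded and
#' counted in the `excluded` column.
#'
#' @param predictions A `rhoterm_predictions` data frame.
#' @param tracks Coverage as returned by [read_coverage()]: a named list
#'   (by record id) of per-base vectors, or of `list(plus =, minus =)`
#'   pairs for strand-specific data.
#' @param min_reads Expression gate on the upstream read value.
#' @param min_drop Minimum fold-decrease for validation.
#' @return The prediction table with added columns `upstream_value`,
#'   `downstream_value`, `read_ratio`, `expressed`, `validated`,
#'   `excluded`; the attribute `percent_validated` gives
#'   100 * validated / expressed.
#' @export
validate_with_coverage <- function(predictions, tracks, min_reads = 10,
                                   min_drop = 1.5) {
  df <- as.data.frame(predictions)
  n <- nrow(df)
  up <- down <- ratio <- rep(NA_real_, n)
  expressed <- validated <- rep(NA, n)
  excluded <- rep(FALSE, n)
  for (i in seq_len(n)) {
    track <- tracks[[df$record_id[i]]]
    if (is.null(track)) {
      stop("no coverage track for record ", df$record_id[i], call. = FALSE)
    }
    v <- track_values(track, df$strand[i])
    len <- length(v)
    if (df$strand[i] == "+") {
      up_pos <- df$rut_start[i]          # RUT 5' end on the scanned strand
      down_pos <- df$rut_end[i] + 150L
    } else {
      up_pos <- df$rut_end[i]
      down_pos <- df$rut_start[i] - 150L
    }
    if (down_pos < 1L || down_pos > len) {
      excluded[i] <- TRUE
      next
    }
    up[i] <- v[up_pos]
    down[i] <- v[down_pos]
    expressed[i] <- up[i] >= min_reads
    ratio[i] <- if (down[i] == 0) {
      if (up[i] > 0) Inf else NA_real_
    } else {
      up[i] / down[i]
    }
    validated[i] <- isTRUE(expressed[i]) && isTRUE(ratio[i] >= min_drop)
  }
  n_excl <- sum(excluded)
  if (n_excl > 0L) {
    message(sprintf("%d prediction(s) excluded: downstream point beyond record",
                    n_excl))
  }
  df$upstream_value <- up
  df$downstream_value <- down
  df$read_ratio <- ratio
  df$expressed <- expressed
  df$validated <- validated
  df$excluded <- excluded
  n_expr <- sum(expressed, na.rm = TRUE)
  attr(df, "percent_validated") <-
    if (n_expr > 0L) 100 * sum(validated, na.rm = TRUE) / n_expr else NA_real_
  df
}

#' Count predictions of one set near predictions of another
#'
#' Counts the intervals of `set_b` having at least one interval of
#' `set_a` within `window` nt (edge-to-edge gap; intersecting intervals
#' have gap 0).  Each `set_b` interval is counted at most once.
#'
#' @param set_a,set_b Data frames with columns `record_id`, `start`,
#'   `end` (1-based inclusive, forward coordinates).
#' @param window Maximum gap in nt (default 50).
#' @return A list with `count`, `n_b` (size of `set_b`) and `percent`
#'   (= 100 * count / n_b).
#' @export
overlap_count <- function(set_a, set_b, window = 50L) {
  n_b <- nrow(set_b)
  if (n_b == 0L) return(list(count = 0L, n_b = 0L, percent = NA_real_))
  if (nrow(set_a) == 0L) {
    return(list(count = 0L, n_b = n_b, percent = 0))
  }
  gr_a <- GenomicRanges::GRanges(set_a$record_id,
                                 IRanges::IRanges(set_a$start, set_a$end))
  gr_b <- GenomicRanges::GRanges(set_b$record_id,
                                 IRanges::IRanges(set_b$start, set_b$end))
  hits <- GenomicRanges::distanceToNearest(gr_b, gr_a)
  near <- S4Vectors::mcols(hits)$distance <= window
  count <- length(unique(S4Vectors::queryHits(hits)[near]))
  list(count = count, n_b = n_b, percent = 100 * count / n_b)
}
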