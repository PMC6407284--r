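## Two-step terminator scan.
##
## Step 1 seeds a 78-nt window with C/G ratio > 1 and regularly spaced
## cytosines, then refines within a 128-nt block (the seed plus 50 nt of
## slack) to the qualifying window of maximal C/G ratio.  Step 2 searches
## the 150 nt downstream of the RUT 3' end for an RNAP pause site: a
## GC-rich stem-loop hairpin and/or the G(-11)G(-10)(C/T)(-1)G(+1)
## consensus element.

RUT_LEN <- 78L
REFINE_SLACK <- 50L   # refinement block = RUT_LEN + 50 = 128 nt
PAUSE_REGION <- 150L
MAX_C_GAP <- 13L

## Per-sequence window statistics: cumulative C/G counts give every
## 78-nt window's composition in O(n).  The spacing criterion is also
## precomputed for all windows at once: the boundary-inclusive maximum
## cytosine gap exceeds 13 exactly when some maximal cytosine-free run
## intersects the window in at least 13 positions, so each long run marks
## a contiguous range of failing window starts.
window_stats <- function(s) {
  n <- nchar(s)
  nw <- n - RUT_LEN + 1L
  if (nw < 1L) {
    return(list(n = n, nw = 0L))
  }
  ch <- seq_chars(s)
  cumC <- cumsum(ch == "C")
  cumG <- cumsum(ch == "G")
  winC <- cumC[RUT_LEN:n] - c(0L, cumC[seq_len(nw - 1L)])
  winG <- cumG[RUT_LEN:n] - c(0L, cumG[seq_len(nw - 1L)])
  r <- rle(ch != "C")
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  gap_bad <- rep(FALSE, nw)
  for (j in which(r$values & r$lengths >= MAX_C_GAP)) {
    i1 <- max(1L, run_start[j] - (RUT_LEN - MAX_C_GAP))
    i2 <- min(nw, run_end[j] - MAX_C_GAP + 1L)
    if (i1 <= i2) gap_bad[i1:i2] <- TRUE
  }
  list(n = n, nw = nw, winC = winC, winG = winG,
       cpos = which(ch == "C"), qual = winC > winG & !gap_bad)
}

## boundary-inclusive gap structure of the window starting at i
window_gaps <- function(st, i) {
  lo <- findInterval(i - 1L, st$cpos) + 1L
  hi <- findInterval(i + RUT_LEN - 1L, st$cpos)
  if (hi < lo) {
    return(list(first = RUT_LEN + 1L, inner = integer(0), last = RUT_LEN + 1L))
  }
  p <- st$cpos[lo:hi] - i + 1L
  list(first = p[1L], inner = diff(p), last = RUT_LEN - p[length(p)] + 1L)
}

## band reading: gaps between consecutive cytosines must also be >= 11 nt
band_ok <- function(st, i) {
  g <- window_gaps(st, i)
  !length(g$inner) || all(g$inner >= 11L)
}

window_max_gap <- function(st, i) {
  g <- window_gaps(st, i)
  max(g$first, g$last, if (length(g$inner)) max(g$inner) else 0L)
}

window_ratio <- function(st, i) {
  if (st$winG[i] == 0L) {
    if (st$winC[i] > 0L) Inf else 0
  } else {
    st$winC[i] / st$winG[i]
  }
}

window_qualifies <- function(st, i, band = FALSE) {
  st$qual[i] && (!band || band_ok(st, i))
}

next_seed <- function(st, from, band = FALSE) {
  if (st$nw < 1L) return(NA_integer_)
  from <- max(1L, as.integer(from))
  if (from > st$nw) return(NA_integer_)
  idx <- which(st$qual)
  idx <- idx[idx >= from]
  if (!band) {
    return(if (length(idx)) idx[1L] else NA_integer_)
  }
  for (i in idx) {
    if (band_ok(st, i)) return(i)
  }
  NA_integer_
}

refine_seed <- function(st, seed, band = FALSE) {
  if (!window_qualifies(st, seed, band)) {
    stop("seed window does not satisfy the RUT criteria", call. = FALSE)
  }
  cand <- seed:min(seed + REFINE_SLACK, st$nw)
  cand <- cand[st$qual[cand]]
  if (band) cand <- cand[vapply(cand, function(i) band_ok(st, i), logical(1L))]
  ratios <- ifelse(st$winG[cand] == 0L,
                   ifelse(st$winC[cand] > 0L, Inf, 0),
                   st$winC[cand] / st$winG[cand])
  best <- cand[which.max(ratios)]   # first maximum: earliest start wins ties
  list(start = best, end = best + RUT_LEN - 1L,
       cg_ratio = window_ratio(st, best),
       max_c_gap = window_max_gap(st, best))
}

#' Find the next RUT seed window
#'
#' Slides a 78-nt window one nucleotide at a time from `from` and returns
#' the first start position whose window has C/G ratio > 1 *and* a
#' boundary-inclusive maximum cytosine gap of at most 13 nt.
#'
#' @param record A [genome_record()] or a plain nucleotide string.
#' @param from 1-based start position at which to begin scanning.
#' @param spacing_band If `TRUE`, additionally require gaps between
#'   consecutive cytosines to be at least 11 nt (the strict band reading
#'   of "every 11--13 nt"); the default accepts denser cytosines.
#' @return 1-based start index of the seed window, or `NA` if no window
#'   qualifies before the end of the sequence.
#' @seealso [refine_rut()], [scan_record()]
#' @export
rut_seed_scan <- function(record, from = 1L, spacing_band = FALSE) {
  st <- window_stats(as_sequence(record))
  next_seed(st, from, spacing_band)
}

#' Refine a RUT seed to the best window in its 128-nt block
#'
#' Among the 51 candidate 78-nt windows starting at `seed .. seed + 50`
#' (truncated at the sequence end), restricted to those satisfying both
#' RUT criteria, returns the window with maximal C/G ratio; ties are
#' broken by the smallest start.
#'
#' @inheritParams rut_seed_scan
#' @param seed A seed position previously returned by [rut_seed_scan()].
#' @return An object of class `rut_site`: a list with `start`, `end`
#'   (1-based inclusive, width exactly 78), `strand`, `cg_ratio` and
#'   `max_c_gap`.
#' @export
refine_rut <- function(record, seed, spacing_band = FALSE) {
  st <- window_stats(as_sequence(record))
  if (is.na(seed) || seed < 1L || st$nw < 1L || seed > st$nw) {
    stop("seed out of range", call. = FALSE)
  }
  r <- refine_seed(st, seed, spacing_band)
  structure(c(r[c("start", "end")], list(strand = "+"),
              r[c("cg_ratio", "max_c_gap")]),
            class = "rut_site")
}

#' @export
print.rut_site <- function(x, ...) {
  cat(sprintf("<rut_site> [%d, %d] (%s) C/G = %.3f, max C gap = %d\n",
              x$start, x$end, x$strand, x$cg_ratio, x$max_c_gap))
  invisible(x)
}

## Watson-Crick complement; N has no partner and never pairs.
WC <- c(A = "T", C = "G", G = "C", T = "A")

#' Find stem-loop hairpins in a pause-search region
#'
#' Enumerates all inverted repeats with a perfect Watson--Crick stem of at
#' least 4 bp (no wobble pairs, no bulges), a loop of 4--8 nt, and a stem
#' GC percentage of at least `genome_gc` (the operational reading of
#' "GC-rich", since the scoring bonuses are tiered at 10 and 20 points
#' above whole-genome GC).  For each (loop position, loop length) only the
#' maximal stem is reported, so nested truncations of the same hairpin do
#' not inflate the candidate list.
#'
#' @param region Nucleotide string (the up-to-150-nt pause-search region).
#' @param genome_gc Whole-genome GC percentage used as the GC-rich
#'   reference scale.
#' @return A data frame with columns `start`, `end` (1-based inclusive
#'   within `region`), `stem_len`, `loop_len` and `stem_gc_percent`,
#'   sorted by start; zero rows when no hairpin qualifies.
#' @export
find_hairpins <- function(region, genome_gc) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      stem_gc_percent = numeric(0))
  n <- nchar(region)
  if (n < 2L * 4L + 4L) return(empty)
  ch <- seq_chars(region)
  comp <- unname(WC[ch])            # NA for N: never pairs
  cumGC <- c(0L, cumsum(ch == "G" | ch == "C"))
  rows <- vector("list", 0L)
  for (loop_len in 4:8) {
    if (n < loop_len + 2L) next
    left <- 1:(n - loop_len - 1L)       # last base of the 5' arm
    right <- left + loop_len + 1L       # first base of the 3' arm
    # grow all stems in lockstep, one pairing step per iteration
    stem <- integer(length(left))
    alive <- seq_along(left)
    k <- 0L
    while (length(alive)) {
      la <- left[alive] - k
      ra <- right[alive] + k
      ok <- la >= 1L & ra <= n
      cc <- comp[la[ok]]
      ok[ok] <- !is.na(cc) & cc == ch[ra[ok]]
      stem[alive[ok]] <- k + 1L
      alive <- alive[ok]
      k <- k + 1L
    }
    for (j in which(stem >= 4L)) {
      s_len <- stem[j]
      a <- left[j] - s_len + 1L
      stem_gc <- 100 * (cumGC[left[j] + 1L] - cumGC[a]) / s_len
      if (stem_gc >= genome_gc) {
        rows[[length(rows) + 1L]] <- list(
          start = a, end = right[j] + s_len - 1L,
          stem_len = s_len, loop_len = loop_len, stem_gc_percent = stem_gc)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find RNAP pause consensus elements
#'
#' Matches every occurrence of the 12-nt pause-inducing consensus
#' G(-11) G(-10) N8 (C/T)(-1) G(+1): a G at the first two positions, eight
#' arbitrary unambiguous bases, C or T at position 11, and G at position
#' 12.  Overlapping matches are all reported; `N` never matches.
#'
#' @param region Nucleotide string.
#' @return Data frame with columns `start` and `end` (1-based inclusive,
#'   `end = start + 11`).
#' @export
find_consensus_elements <- function(region) {
  m <- gregexpr("(?=GG[ACGT]{8}[CT]G)", region, perl = TRUE)[[1L]]
  starts <- as.integer(m)
  if (length(starts) == 0L || starts[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = starts, end = starts + 11L)
}

#' Select the pause site for a candidate RUT
#'
#' Applies the pause-site decision rule to the region downstream of a RUT
#' 3' end.  When hairpins are present the hairpin maximising the final
#' prediction score is chosen (its stem-GC tier, loop/stem half-point
#' bonuses, and the +3 bonus for a consensus element lying within the
#' hairpin span extended by 5 nt on each side), ties broken by smallest
#' start.  With no hairpin but at least one consensus element, the
#' earliest consensus match is returned alone.  With neither, `NULL` is
#' returned and the candidate RUT is discarded.
#'
#' @inheritParams find_hairpins
#' @return An object of class `pause_site` (fields `hairpin`, `consensus`,
#'   `proximal`, `type`, `start`, `end`) or `NULL`.
#' @export
select_pause_site <- function(region, genome_gc) {
  if (!nzchar(region)) return(NULL)
  hp <- find_hairpins(region, genome_gc)
  cons <- find_consensus_elements(region)
  if (nrow(hp) > 0L) {
    nh <- nrow(hp)
    bonus <- numeric(nh)
    prox_idx <- rep(NA_integer_, nh)
    for (k in seq_len(nh)) {
      prox <- which(cons$start >= hp$start[k] - 5L & cons$end <= hp$end[k] + 5L)
      if (length(prox)) prox_idx[k] <- prox[1L]
      bonus[k] <- stem_gc_bonus(hp$stem_gc_percent[k], genome_gc) +
        0.5 * (hp$loop_len[k] < 6L) + 0.5 * (hp$stem_len[k] > 4L) +
        3 * (length(prox) > 0L)
    }
    k <- which.max(bonus)   # hp is start-sorted: first max = smallest start
    proximal <- !is.na(prox_idx[k])
    consensus <- if (proximal) cons[prox_idx[k], , drop = FALSE] else NULL
    structure(list(
      hairpin = hp[k, , drop = FALSE],
      consensus = consensus,
      proximal = proximal,
      type = if (proximal) "hairpin+consensus" else "hairpin",
      start = if (proximal) min(hp$start[k], consensus$start) else hp$start[k],
      end = if (proximal) max(hp$end[k], consensus$end) else hp$end[k]
    ), class = "pause_site")
  } else if (nrow(cons) > 0L) {
    structure(list(hairpin = NULL, consensus = cons[1L, , drop = FALSE],
                   proximal = FALSE, type = "consensus",
                   start = cons$start[1L], end = cons$end[1L]),
              class = "pause_site")
  } else {
    NULL
  }
}

empty_predictions <- function() {
  structure(
    data.frame(record_id = character(0), strand = character(0),
               rut_start = integer(0), rut_end = integer(0),
               cg_ratio = numeric(0), max_c_gap = integer(0),
               pause_type = character(0),
               pause_start = integer(0), pause_end = integer(0),
               stem_len = integer(0), loop_len = integer(0),
               stem_gc_percent = numeric(0),
               consensus_start = integer(0), consensus_end = integer(0),
               score = numeric(0), cg_bonus = numeric(0),
               stem_gc_bonus = numeric(0), loop_bonus = numeric(0),
               stem_len_bonus = numeric(0), consensus_bonus = numeric(0)),
    class = c("rhoterm_predictions", "data.frame"))
}

## scan one strand in its own coordinates; returns list(df, n_seeds)
scan_strand <- function(s, genome_gc, spacing_band = FALSE) {
  st <- window_stats(s)
  rows <- list()
  n_seeds <- 0L
  pos <- 1L
  if (st$nw >= 1L) {
    repeat {
      seed <- next_seed(st, pos, spacing_band)
      if (is.na(seed)) break
      n_seeds <- n_seeds + 1L
      rut <- refine_seed(st, seed, spacing_band)
      region_start <- rut$end + 1L
      region_end <- min(st$n, rut$end + PAUSE_REGION)
      pause <- NULL
      if (region_start <= region_end) {
        pause <- select_pause_site(substr(s, region_start, region_end),
                                   genome_gc)
      }
      if (is.null(pause)) {
        pos <- seed + 1L      # discarded: resume conservatively at seed + 1
        next
      }
      sc <- score_prediction(
        structure(c(rut[c("start", "end")], list(strand = "+"),
                    rut[c("cg_ratio", "max_c_gap")]), class = "rut_site"),
        pause, genome_gc)
      off <- region_start - 1L
      hp <- pause$hairpin
      cs <- pause$consensus
      rows[[length(rows) + 1L]] <- data.frame(
        rut_start = rut$start, rut_end = rut$end,
        cg_ratio = rut$cg_ratio, max_c_gap = rut$max_c_gap,
        pause_type = pause$type,
        pause_start = off + pause$start, pause_end = off + pause$end,
        stem_len = if (is.null(hp)) NA_integer_ else hp$stem_len,
        loop_len = if (is.null(hp)) NA_integer_ else hp$loop_len,
        stem_gc_percent = if (is.null(hp)) NA_real_ else hp$stem_gc_percent,
        consensus_start = if (is.null(cs)) NA_integer_ else off + cs$start,
        consensus_end = if (is.null(cs)) NA_integer_ else off + cs$end,
        score = sc$total, cg_bonus = sc$cg_bonus,
        stem_gc_bonus = sc$stem_gc_bonus, loop_bonus = sc$loop_bonus,
        stem_len_bonus = sc$stem_len_bonus,
        consensus_bonus = sc$consensus_bonus)
      pos <- rut$end + 1L     # success: resume right after the RUT 3' end
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  list(df = df, n_seeds = n_seeds)
}

## map an interval from reverse-complement coordinates back to forward
mirror <- function(start, end, n) {
  list(start = n - end + 1L, end = n - start + 1L)
}

#' Scan one strand of a genome record for Rho-dependent terminators
#'
#' Runs the full two-step procedure on a single strand: RUT seeding and
#' 128-nt refinement, then pause-site selection in the downstream 150 nt,
#' then scoring.  After a successful prediction scanning resumes just
#' after the RUT 3' end (allowing dense adjacent terminators); after a
#' discarded candidate it resumes one nucleotide past the seed, so no
#' region is skipped.  For the minus strand the reverse complement is
#' scanned and all coordinates are mapped back to forward-strand 1-based
#' positions.
#'
#' @param record A [genome_record()] (or a plain nucleotide string, which
#'   is wrapped with id `"query"`).
#' @param strand `"+"` or `"-"`.
#' @param spacing_band See [rut_seed_scan()].
#' @return A `rhoterm_predictions` data frame (possibly zero rows) sorted
#'   by forward-strand `rut_start`; columns include the RUT interval and
#'   composition, the pause-site type and span, hairpin geometry where
#'   present, the total score and its breakdown.
#' @export
scan_record <- function(record, strand = c("+", "-"), spacing_band = FALSE) {
  strand <- match.arg(strand)
  if (!inherits(record, "genome_record")) {
    record <- genome_record("query", as_sequence(record))
  }
  s <- record$sequence
  n <- nchar(s)
  if (strand == "+") {
    res <- scan_strand(s, record$gc_percent, spacing_band)
    df <- res$df
  } else {
    res <- scan_strand(revcomp(s), record$gc_percent, spacing_band)
    df <- res$df
    if (!is.null(df)) {
      for (cols in list(c("rut_start", "rut_end"),
                        c("pause_start", "pause_end"),
                        c("consensus_start", "consensus_end"))) {
        m <- mirror(df[[cols[1L]]], df[[cols[2L]]], n)
        df[[cols[1L]]] <- m$start
        df[[cols[2L]]] <- m$end
      }
    }
  }
  if (is.null(df)) {
    out <- empty_predictions()
    attr(out, "n_seeds") <- res$n_seeds
    return(out)
  }
  df <- cbind(record_id = record$id, strand = strand, df)
  df <- df[order(df$rut_start, df$rut_end), , drop = FALSE]
  rownames(df) <- NULL
  out <- structure(df, class = c("rhoterm_predictions", "data.frame"))
  attr(out, "n_seeds") <- res$n_seeds
  out
}

#' Scan genome records on one or both strands
#'
#' Convenience driver over [scan_record()] for one record or a list of
#' records, optionally filtering by a minimum score.
#'
#' @param records A [genome_record()] or a list of them (e.g. from
#'   [read_fasta()]).
#' @param strand `"both"`, `"+"` or `"-"`.
#' @param min_score Optional lower score bound; predictions scoring below
#'   it are dropped.
#' @param spacing_band See [rut_seed_scan()].
#' @param verbose If `TRUE`, log per-record progress (id, length, number
#'   of seeds and of predictions) to standard error.
#' @return A `rhoterm_predictions` data frame sorted by record then
#'   forward-strand start.
#' @examples
#' rec <- genome_record("toy", strrep("ACGTT", 100))
#' nrow(scan_genome(rec))
#' @export
scan_genome <- function(records, strand = c("both", "+", "-"),
                        min_score = NULL, spacing_band = FALSE,
                        verbose = FALSE) {
  strand <- match.arg(strand)
  if (inherits(records, "genome_record")) records <- list(records)
  strands <- if (strand == "both") c("+", "-") else strand
  parts <- list()
  for (rec in records) {
    n_seeds <- 0L
    n_pred <- 0L
    for (sd in strands) {
      p <- scan_record(rec, sd, spacing_band)
      n_seeds <- n_seeds + attr(p, "n_seeds")
      n_pred <- n_pred + nrow(p)
      if (nrow(p)) parts[[length(parts) + 1L]] <- as.data.frame(p)
    }
    if (verbose) {
      message(sprintf("record %s: %d nt, %d seeds, %d predictions",
                      rec$id, nchar(rec$sequence), n_seeds, n_pred))
    }
  }
  df <- if (length(parts)) do.call(rbind, parts) else
    as.data.frame(empty_predictions())
  if (!is.null(min_score)) df <- df[df$score >= min_score, , drop = FALSE]
  df <- df[order(df$record_id, df$rut_start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("rhoterm_predictions", "data.frame"))
}

#' @export
print.rhoterm_predictions <- function(x, ...) {
  cat(sprintf("<rhoterm_predictions> %d prediction(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- as.data.frame(x)[, c("record_id", "strand", "rut_start",
                                 "rut_end", "cg_ratio", "pause_type",
                                 "pause_start", "pause_end", "score")]
    show$cg_ratio <- round(show$cg_ratio, 3)
    print(utils::head(show, 10L))
    if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.rhoterm_predictions <- function(object, ...) {
  cat(sprintf("%d prediction(s) on %d record(s)\n",
              nrow(object), length(unique(object$record_id))))
  if (nrow(object)) {
    cat("pause types:\n")
    print(table(object$pause_type))
    cat(sprintf("score: min %.1f, median %.1f, max %.1f\n",
                min(object$score), stats::median(object$score),
                max(object$score)))
    cat(sprintf("C/G ratio (finite): mean %.2f\n",
                mean(object$cg_ratio[is.finite(object$cg_ratio)])))
  }
  invisible(object)
}
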