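# Brute-force oracles, kept deliberately independent of the package
# internals: plain loops, direct character comparison, no shared helpers.

random_seq <- function(n, gc = 50) {
  p <- c(A = (100 - gc) / 200, C = gc / 200, G = gc / 200,
         T = (100 - gc) / 200)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

oracle_cg_ratio <- function(w) {
  ch <- strsplit(w, "")[[1]]
  nc <- 0L
  ng <- 0L
  for (b in ch) {
    if (b == "C") nc <- nc + 1L
    if (b == "G") ng <- ng + 1L
  }
  if (ng == 0L) {
    if (nc > 0L) Inf else 0
  } else {
    nc / ng
  }
}

oracle_max_c_gap <- function(w) {
  ch <- strsplit(w, "")[[1]]
  L <- length(ch)
  pos <- integer(0)
  for (i in seq_len(L)) if (ch[i] == "C") pos <- c(pos, i)
  if (length(pos) == 0L) return(L + 1L)
  gaps <- pos[1L]
  if (length(pos) > 1L) {
    for (k in 2:length(pos)) gaps <- c(gaps, pos[k] - pos[k - 1L])
  }
  gaps <- c(gaps, L - pos[length(pos)] + 1L)
  max(gaps)
}

# 1-based starts of all 78-nt windows satisfying both RUT criteria
oracle_qualifying_windows <- function(s) {
  n <- nchar(s)
  out <- integer(0)
  if (n < 78L) return(out)
  for (i in 1:(n - 77L)) {
    w <- substr(s, i, i + 77L)
    if (oracle_cg_ratio(w) > 1 && oracle_max_c_gap(w) <= 13L) {
      out <- c(out, i)
    }
  }
  out
}

oracle_revcomp1 <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# every (loop position, loop length, stem length) by direct
# reverse-complement comparison; maximal stem per (position, length),
# then the GC-rich filter
oracle_hairpins <- function(region, genome_gc) {
  n <- nchar(region)
  rows <- list()
  for (loop_len in 4:8) {
    if (n < loop_len + 2L) next
    for (loop_start in 2:(n - loop_len)) {
      best <- 0L
      max_stem <- min(loop_start - 1L, n - loop_start - loop_len + 1L)
      for (stem in seq_len(max_stem)) {
        arm1 <- substr(region, loop_start - stem, loop_start - 1L)
        arm2 <- substr(region, loop_start + loop_len,
                       loop_start + loop_len + stem - 1L)
        if (!grepl("N", arm1) && !grepl("N", arm2) &&
            arm2 == oracle_revcomp1(arm1)) {
          best <- stem
        }
      }
      if (best >= 4L) {
        arm1 <- substr(region, loop_start - best, loop_start - 1L)
        gc <- 100 * sum(strsplit(arm1, "")[[1]] %in% c("G", "C")) / best
        if (gc >= genome_gc) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = loop_start - best,
            end = loop_start + loop_len + best - 1L,
            stem_len = best, loop_len = loop_len, stem_gc_percent = gc)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      stem_gc_percent = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_consensus <- function(region) {
  ch <- strsplit(region, "")[[1]]
  n <- length(ch)
  out <- integer(0)
  if (n >= 12L) {
    for (i in 1:(n - 11L)) {
      if (ch[i] == "G" && ch[i + 1L] == "G" &&
          ch[i + 10L] %in% c("C", "T") && ch[i + 11L] == "G" &&
          all(ch[i:(i + 11L)] %in% c("A", "C", "G", "T"))) {
        out <- c(out, i)
      }
    }
  }
  out
}

# all-pairs interval gap counting (1-based inclusive intervals)
oracle_overlap_count <- function(set_a, set_b, window = 50L) {
  count <- 0L
  for (j in seq_len(nrow(set_b))) {
    hit <- FALSE
    for (i in seq_len(nrow(set_a))) {
      if (set_a$record_id[i] != set_b$record_id[j]) next
      gap <- max(set_a$start[i], set_b$start[j]) -
        min(set_a$end[i], set_b$end[j]) - 1L
      if (gap < 0L) gap <- 0L
      if (gap <= window) { hit <- TRUE; break }
    }
    if (hit) count <- count + 1L
  }
  count
}

# predictions whose RUT overlaps a planted RUT on the same strand
planted_hits <- function(pred, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    any(pred$strand == truth$strand[i] &
          pred$rut_start <= truth$rut_end[i] &
          pred$rut_end >= truth$rut_start[i])
  }, logical(1L))
}

planted_prediction_rows <- function(pred, truth) {
  keep <- rep(FALSE, nrow(pred))
  for (i in seq_len(nrow(truth))) {
    keep <- keep | (pred$strand == truth$strand[i] &
                      pred$rut_start <= truth$rut_end[i] &
                      pred$rut_end >= truth$rut_start[i])
  }
  which(keep)
}
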