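## Seeded synthetic fixtures: background genomes with planted RUT +
## hairpin terminators, truth tables, and piecewise coverage tracks with
## multiplicative step-downs.  These emulate exactly the structure the
## scanner detects, so every module is testable offline.

#' Specify a synthetic genome fixture
#'
#' Bundles and validates the parameters of the synthetic-genome
#' generator.  Defaults describe a clearly detectable configuration: a
#' GC-40% background with planted terminators of C/G ratio 2, cytosines
#' every 12 nt, a perfect 6-bp-stem / 4-nt-loop hairpin 20 nt downstream
#' of the RUT.
#'
#' @param background_gc Background GC percentage.
#' @param length Genome length in nt.
#' @param n_terminators Number of planted terminators.
#' @param rut_cg_ratio_target Target C/G ratio of planted RUT windows
#'   (must exceed 1).
#' @param c_spacing Cytosine spacing of planted RUTs, 11--13 nt.
#' @param hairpin_stem_len Planted stem length in bp (>= 4; >= 7 when
#'   `include_consensus`).
#' @param hairpin_loop_len Planted loop length, 4--8 nt.
#' @param include_consensus Plant a pause consensus element overlapping
#'   the hairpin so that proximity holds.
#' @param rut_to_pause_gap Background nt between the RUT 3' end and the
#'   hairpin; the gap plus the hairpin span must stay within the 150-nt
#'   pause-search region.
#' @param seed Integer seed; fixes the genome exactly.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(background_gc = 40, length = 20000L,
                         n_terminators = 5L, rut_cg_ratio_target = 2,
                         c_spacing = 12L, hairpin_stem_len = 6L,
                         hairpin_loop_len = 4L, include_consensus = FALSE,
                         rut_to_pause_gap = 20L, seed = 1L) {
  if (rut_cg_ratio_target <= 1) {
    stop("rut_cg_ratio_target must exceed 1 (a RUT has C > G content)",
         call. = FALSE)
  }
  if (c_spacing < 1L || c_spacing > 13L) {
    stop("c_spacing must be at most 13 nt", call. = FALSE)
  }
  if (hairpin_loop_len < 4L || hairpin_loop_len > 8L) {
    stop("hairpin loop must be 4-8 nt", call. = FALSE)
  }
  if (hairpin_stem_len < 4L) stop("hairpin stem must be >= 4 bp", call. = FALSE)
  if (include_consensus && hairpin_stem_len < 7L) {
    stop("a planted proximal consensus needs a stem of >= 7 bp", call. = FALSE)
  }
  span <- 2L * hairpin_stem_len + hairpin_loop_len +
    if (include_consensus) 5L else 0L
  if (rut_to_pause_gap < 0L || rut_to_pause_gap + span > 150L) {
    stop("rut_to_pause_gap + hairpin span must fit in the 150-nt pause region",
         call. = FALSE)
  }
  structure(list(background_gc = background_gc, length = as.integer(length),
                 n_terminators = as.integer(n_terminators),
                 rut_cg_ratio_target = rut_cg_ratio_target,
                 c_spacing = as.integer(c_spacing),
                 hairpin_stem_len = as.integer(hairpin_stem_len),
                 hairpin_loop_len = as.integer(hairpin_loop_len),
                 include_consensus = isTRUE(include_consensus),
                 rut_to_pause_gap = as.integer(rut_to_pause_gap),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

random_background <- function(n, gc) {
  p <- c(A = (100 - gc) / 200, C = gc / 200, G = gc / 200,
         T = (100 - gc) / 200)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a 78-nt RUT window with prescribed composition
#'
#' Places a cytosine every `c_spacing` nt (guaranteeing the spacing
#' criterion), then fills the remaining positions with G, extra C and A/T
#' so that the measured C/G ratio lands within 0.1 of the target.  The
#' emitted window is re-checked with the core predicates and redrawn on
#' failure (bounded retries).
#'
#' @param rut_cg_ratio_target Target C/G ratio (> 1).
#' @param c_spacing Cytosine spacing, at most 13 nt.
#' @return A 78-nt string.
#' @export
make_rut_window <- function(rut_cg_ratio_target = 2, c_spacing = 12L) {
  if (rut_cg_ratio_target <= 1) {
    stop("rut_cg_ratio_target must exceed 1", call. = FALSE)
  }
  if (c_spacing < 1L || c_spacing > 13L) {
    stop("c_spacing must be at most 13 nt", call. = FALSE)
  }
  base_c <- seq(c_spacing, RUT_LEN, by = c_spacing)
  n_free <- RUT_LEN - length(base_c)
  # choose (extra C count, G count) minimising |C/G - target|
  best <- NULL
  for (extra in 0:(min(30L, n_free))) {
    nc <- length(base_c) + extra
    ng <- round(nc / rut_cg_ratio_target)
    if (ng < 1L || ng > n_free - extra) next
    ratio <- nc / ng
    if (ratio <= 1) next
    err <- abs(ratio - rut_cg_ratio_target)
    if (is.null(best) || err < best$err) best <- list(extra = extra,
                                                      ng = ng, err = err)
  }
  if (is.null(best) || best$err > 0.1) {
    stop("target C/G ratio unreachable at the requested spacing",
         call. = FALSE)
  }
  for (try in 1:50) {
    ch <- rep("", RUT_LEN)
    ch[base_c] <- "C"
    free <- which(ch == "")
    fill <- c(rep("C", best$extra), rep("G", best$ng),
              sample(c("A", "T"), length(free) - best$extra - best$ng,
                     replace = TRUE))
    ch[free] <- sample(fill)
    w <- paste(ch, collapse = "")
    r <- compute_cg_ratio(w)
    if (r > 1 && abs(r - rut_cg_ratio_target) <= 0.1 &&
        max_c_gap(w) <= MAX_C_GAP) {
      return(w)
    }
  }
  stop("failed to construct a qualifying RUT window", call. = FALSE)
}

#' Generate a stem-loop hairpin sequence
#'
#' Builds arm + loop + reverse-complement(arm) with a pure G/C stem arm
#' (stem GC 100%, hence GC-rich against any genomic background) and an
#' A/T loop.  With `include_consensus` the last seven stem positions and
#' a 5-nt tail are arranged so that a pause consensus element lies
#' entirely within the hairpin span extended by 5 nt, making the +3
#' proximity bonus hold by construction.
#'
#' @param stem_len Stem length in bp (>= 4; >= 7 with consensus).
#' @param loop_len Loop length, 4--8 nt.
#' @param include_consensus Embed a proximal consensus element.
#' @return The hairpin string (plus the 5-nt consensus tail when
#'   requested).
#' @export
make_hairpin <- function(stem_len = 6L, loop_len = 4L,
                         include_consensus = FALSE) {
  if (loop_len < 4L || loop_len > 8L) {
    stop("hairpin loop must be 4-8 nt", call. = FALSE)
  }
  if (stem_len < 4L) stop("hairpin stem must be >= 4 bp", call. = FALSE)
  if (include_consensus && stem_len < 7L) {
    stop("a proximal consensus needs a stem of >= 7 bp", call. = FALSE)
  }
  arm <- sample(c("G", "C"), stem_len, replace = TRUE)
  if (include_consensus) {
    # consensus starts 6 nt before the hairpin 3' end: its GG falls on the
    # last arm's positions stem_len-6, stem_len-5, i.e. arm[6], arm[7] = C
    arm[6L] <- "C"
    arm[7L] <- "C"
  }
  loop <- sample(c("A", "T"), loop_len, replace = TRUE)
  hp <- paste(c(arm, loop, rev(unname(WC[arm]))), collapse = "")
  if (include_consensus) {
    tail <- c(sample(c("A", "T"), 3L, replace = TRUE),
              sample(c("C", "T"), 1L), "G")
    hp <- paste0(hp, paste(tail, collapse = ""))
  }
  hp
}

#' Generate a synthetic genome with planted terminators
#'
#' Draws an i.i.d. background at the requested GC percentage and plants
#' `n_terminators` RUT + gap + hairpin elements on random strands,
#' separated by at least 300 nt of background (so upstream extraction
#' windows never collide).  Planted elements are verified post-hoc
#' against the core predicates.
#'
#' @param spec A [fixture_spec()].
#' @param id Record id of the generated genome.
#' @return A list with `record` (a [genome_record()]) and `truth`, a data
#'   frame of planted intervals (forward 1-based coordinates): element,
#'   RUT and pause spans, strand and parameters.
#' @export
generate_genome <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  hp_span <- 2L * spec$hairpin_stem_len + spec$hairpin_loop_len
  elem_len <- RUT_LEN + spec$rut_to_pause_gap + hp_span +
    if (spec$include_consensus) 5L else 0L
  margin <- 400L
  sep <- 300L
  need <- 2L * margin + spec$n_terminators * elem_len +
    max(0L, spec$n_terminators - 1L) * sep
  if (spec$length < need) {
    stop(sprintf("length %d too small for %d terminator(s) (need >= %d)",
                 spec$length, spec$n_terminators, need), call. = FALSE)
  }
  # evenly spaced slots with random jitter inside the slack
  starts <- integer(0)
  if (spec$n_terminators > 0L) {
    slack <- spec$length - need
    jitter <- sort(sample.int(slack + 1L, spec$n_terminators,
                              replace = TRUE) - 1L)
    starts <- margin + 1L + (seq_len(spec$n_terminators) - 1L) *
      (elem_len + sep) + jitter
  }
  s <- random_background(spec$length, spec$background_gc)
  rows <- list()
  for (k in seq_along(starts)) {
    rut <- make_rut_window(spec$rut_cg_ratio_target, spec$c_spacing)
    gap <- if (spec$rut_to_pause_gap > 0L) {
      random_background(spec$rut_to_pause_gap, spec$background_gc)
    } else ""
    hp <- make_hairpin(spec$hairpin_stem_len, spec$hairpin_loop_len,
                       spec$include_consensus)
    construct <- paste0(rut, gap, hp)
    strand <- sample(c("+", "-"), 1L)
    insert <- if (strand == "+") construct else revcomp(construct)
    p <- starts[k]
    L <- nchar(construct)
    substr(s, p, p + L - 1L) <- insert
    if (strand == "+") {
      rut_start <- p; rut_end <- p + RUT_LEN - 1L
      pause_start <- p + RUT_LEN + spec$rut_to_pause_gap
      pause_end <- pause_start + hp_span - 1L
    } else {
      rut_end <- p + L - 1L; rut_start <- rut_end - RUT_LEN + 1L
      pause_end <- rut_start - spec$rut_to_pause_gap - 1L
      pause_start <- pause_end - hp_span + 1L
    }
    stopifnot(compute_cg_ratio(rut) > 1, max_c_gap(rut) <= MAX_C_GAP)
    rows[[k]] <- data.frame(
      terminator = k, strand = strand, element_start = p,
      element_end = p + L - 1L, rut_start = rut_start, rut_end = rut_end,
      pause_start = pause_start, pause_end = pause_end,
      cg_ratio = compute_cg_ratio(rut),
      stem_len = spec$hairpin_stem_len, loop_len = spec$hairpin_loop_len,
      has_consensus = spec$include_consensus)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(terminator = integer(0), strand = character(0),
               element_start = integer(0), element_end = integer(0),
               rut_start = integer(0), rut_end = integer(0),
               pause_start = integer(0), pause_end = integer(0),
               cg_ratio = numeric(0), stem_len = integer(0),
               loop_len = integer(0), has_consensus = logical(0))
  list(record = genome_record(id, s), truth = truth)
}

#' Generate a coverage track with step-downs at planted terminators
#'
#' Coverage equals `expressed_value` everywhere except for a window
#' downstream (in the terminator's own orientation) of each planted
#' pause site, where it is divided by `drop_factor`; optional additive
#' Gaussian noise is truncated at zero.  The drop window is long enough
#' to contain the validator's measurement point 150 nt past the RUT 3'
#' end, and short enough never to reach the next planted element.
#'
#' @param record The [genome_record()] the track belongs to.
#' @param truth Truth table from [generate_genome()].
#' @param expressed_value Baseline coverage (default 20).
#' @param drop_factor Fold-decrease after each pause site (>= 1).
#' @param noise_sd Standard deviation of additive truncated Gaussian
#'   noise (default 0, i.e. a noiseless piecewise track).
#' @return Per-base numeric vector of length `nchar(record$sequence)`.
#' @export
generate_coverage <- function(record, truth, expressed_value = 20,
                              drop_factor = 2, noise_sd = 0) {
  if (drop_factor < 1) stop("drop_factor must be >= 1", call. = FALSE)
  n <- nchar(record$sequence)
  v <- rep(expressed_value, n)
  drop_w <- 250L
  for (i in seq_len(nrow(truth))) {
    if (truth$strand[i] == "+") {
      a <- truth$pause_end[i] + 1L
      b <- min(n, truth$pause_end[i] + drop_w)
    } else {
      a <- max(1L, truth$pause_start[i] - drop_w)
      b <- truth$pause_start[i] - 1L
    }
    if (a <= b) v[a:b] <- v[a:b] / drop_factor
  }
  if (noise_sd > 0) v <- pmax(0, v + rnorm(n, 0, noise_sd))
  v
}
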