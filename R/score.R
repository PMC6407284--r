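## Scoring schedule.  A prediction always earns 3 base points for the RUT
## site and 3 for the pause site.  Bonuses (all comparisons strict, as
## printed; tiers are exclusive):
##   C/G ratio   > 1.25 -> +1, > 1.5 -> +2, > 2 -> +3
##   stem GC%    > genome GC + 10 -> +1, > genome GC + 20 -> +2
##   loop < 6 nt -> +0.5 ; stem > 4 bp -> +0.5 (independent half points)
##   consensus element proximal to the hairpin -> +3
## Range: [6, 15]; 15 = 3 + 3 + 3 + 2 + 0.5 + 0.5 + 3, which forces the
## reading of the two half-point bonuses as independently awardable.

cg_bonus_tier <- function(cg_ratio) {
  if (cg_ratio > 2) 3 else if (cg_ratio > 1.5) 2 else if (cg_ratio > 1.25) 1 else 0
}

stem_gc_bonus <- function(stem_gc, genome_gc) {
  if (stem_gc > genome_gc + 20) 2 else if (stem_gc > genome_gc + 10) 1 else 0
}

#' Score a terminator prediction
#'
#' Applies the fixed 6--15 point schedule to a RUT site / pause site pair.
#' The C/G-ratio and stem-GC bonuses award only their highest applicable
#' tier; the loop-length and stem-length half points are independent; the
#' +3 consensus bonus requires the consensus element to be proximal to a
#' hairpin (a consensus-only pause site earns base points but never the
#' +3).  Pause sites without a hairpin receive no hairpin-derived bonus.
#'
#' @param rut A `rut_site` (or list with at least `cg_ratio`; if `start`
#'   and `end` are present the 78-nt width is checked).
#' @param pause A `pause_site` as returned by [select_pause_site()] (or a
#'   list with `hairpin`, `consensus`, `proximal`).
#' @param genome_gc Whole-genome GC percentage.
#' @return An object of class `score_breakdown`: base points, each bonus,
#'   and `total`.
#' @examples
#' rut <- list(cg_ratio = 2.5)
#' pause <- list(hairpin = data.frame(stem_len = 6, loop_len = 4,
#'                                    stem_gc_percent = 90),
#'               consensus = data.frame(start = 1, end = 12),
#'               proximal = TRUE)
#' score_prediction(rut, pause, genome_gc = 50)$total  # 15
#' @export
score_prediction <- function(rut, pause, genome_gc) {
  if (!is.list(rut) || is.null(rut$cg_ratio)) {
    stop("rut must carry a cg_ratio", call. = FALSE)
  }
  if (!(rut$cg_ratio > 1)) {
    stop("RUT C/G ratio must exceed 1", call. = FALSE)
  }
  if (!is.null(rut$start) && !is.null(rut$end) &&
      rut$end - rut$start + 1L != 78L) {
    stop("RUT site must be exactly 78 nt", call. = FALSE)
  }
  hp <- pause$hairpin
  if (is.null(hp) && is.null(pause$consensus)) {
    stop("pause site must contain a hairpin or a consensus element",
         call. = FALSE)
  }
  proximal <- isTRUE(pause$proximal)
  if (proximal && (is.null(hp) || is.null(pause$consensus))) {
    stop("consensus proximity requires both a hairpin and a consensus element",
         call. = FALSE)
  }
  if (!is.null(hp)) {
    if (hp$stem_len < 4L) stop("hairpin stem must be >= 4 bp", call. = FALSE)
    if (hp$loop_len < 4L || hp$loop_len > 8L) {
      stop("hairpin loop must be 4-8 nt", call. = FALSE)
    }
  }
  b <- list(
    base_rut = 3, base_pause = 3,
    cg_bonus = cg_bonus_tier(rut$cg_ratio),
    stem_gc_bonus = if (is.null(hp)) 0 else
      stem_gc_bonus(hp$stem_gc_percent, genome_gc),
    loop_bonus = if (is.null(hp)) 0 else 0.5 * (hp$loop_len < 6L),
    stem_len_bonus = if (is.null(hp)) 0 else 0.5 * (hp$stem_len > 4L),
    consensus_bonus = if (proximal) 3 else 0
  )
  b$total <- b$base_rut + b$base_pause + b$cg_bonus + b$stem_gc_bonus +
    b$loop_bonus + b$stem_len_bonus + b$consensus_bonus
  structure(b, class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(paste0("<score_breakdown> total %.1f = 3 (RUT) + 3 (pause)",
                     " + %g (C/G) + %g (stem GC) + %g (loop) + %g (stem len)",
                     " + %g (consensus)\n"),
              x$total, x$cg_bonus, x$stem_gc_bonus, x$loop_bonus,
              x$stem_len_bonus, x$consensus_bonus))
  invisible(x)
}
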