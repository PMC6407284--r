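#' C/G ratio of a window
#'
#' The scalar proxy for "C > G content" of a candidate RUT site: the count
#' of C residues divided by the count of G residues.  A window with no G
#' but at least one C has a ratio of `Inf` (it trivially satisfies any
#' "ratio > 1" test); a window with neither C nor G returns 0 and never
#' qualifies.  `N` counts as neither C nor G.
#'
#' @param window Non-empty nucleotide string.
#' @return Nonnegative number, possibly `Inf`.
#' @examples
#' compute_cg_ratio("CCG")   # 2
#' compute_cg_ratio("CCCC")  # Inf
#' @export
compute_cg_ratio <- function(window) {
  ch <- check_window(window)
  nc <- sum(ch == "C")
  ng <- sum(ch == "G")
  if (ng == 0L) {
    if (nc > 0L) Inf else 0
  } else {
    nc / ng
  }
}

#' Maximum cytosine gap of a window
#'
#' Largest boundary-inclusive spacing between consecutive cytosines: the
#' maximum over the distance from the window start to the first C, all
#' gaps between consecutive Cs, and the distance from the last C to the
#' window end (both boundaries counted as if flanking virtual cytosines
#' just outside the window).  A window with no C at all returns
#' `length + 1`.  The "regularly spaced cytosines" criterion of the RUT
#' site is satisfied when this value is at most 13 nt.
#'
#' @param window Non-empty nucleotide string.
#' @return Integer number of nucleotides.
#' @examples
#' # C every 12 nt starting at the first base of a 78-mer
#' w <- paste(rep(c("C", strrep("A", 11)), length.out = 78), collapse = "")
#' @export
max_c_gap <- function(window) {
  ch <- check_window(window)
  n <- length(ch)
  p <- which(ch == "C")
  if (length(p) == 0L) return(n + 1L)
  inner <- if (length(p) > 1L) max(diff(p)) else 0L
  max(p[1L], inner, n - p[length(p)] + 1L)
}

check_window <- function(window) {
  if (!is.character(window) || length(window) != 1L || !nzchar(window)) {
    stop("window must be a single non-empty string", call. = FALSE)
  }
  seq_chars(window)
}
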