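#' Cost of a given alignment
#'
#' Sums the column costs `C(top[i], bottom[i])` of a pair-wise alignment
#' under a cost model.
#'
#' @param aln A [pairwise_alignment()].
#' @param costs A [cost_model()] (default unit costs).
#' @return Numeric cost.
#' @examples
#' alignment_cost(pairwise_alignment("actg---g", "a-tgagag"))  # 4
#' @export
alignment_cost <- function(aln, costs = cost_model()) {
  stopifnot(inherits(aln, "pairwise_alignment"), inherits(costs, "cost_model"))
  if (aln$length == 0L) return(0)
  sum(column_cost(costs, chars(aln$top), chars(aln$bottom)))
}

# Shared front end: encode two sequences and run a kernel.
edit_dp <- function(a, b, costs, traceback, banded, case_fold = TRUE) {
  a <- norm_seq(a, case_fold); b <- norm_seq(b, case_fold)
  if (grepl(GAP, a, fixed = TRUE) || grepl(GAP, b, fixed = TRUE))
    stop("sequences must not contain the gap symbol '-'")
  syms <- observed_symbols(c(a, b))
  enc <- encode_strings(c(a, b), syms)
  cm <- cost_matrix_for(costs, syms)
  if (banded) {
    t0 <- max(1, abs(nchar(a) - nchar(b)) * costs$indel)
    raw <- cpp_edit_banded(enc[[1L]], enc[[2L]], cm, t0,
                           min_positive_cost(cm), traceback)
  } else {
    raw <- cpp_edit_full(enc[[1L]], enc[[2L]], cm, traceback)
  }
  out <- new_dip_distance(raw$distance,
                          if (banded) "banded_edit_distance" else "edit_distance")
  if (traceback) {
    top <- decode_ints(raw$top, syms); bot <- decode_ints(raw$bottom, syms)
    out$alignment <-
      if (nchar(top) > 0) pairwise_alignment(top, bot, case_fold = FALSE)
      else structure(list(top = "", bottom = "", length = 0L),
                     class = "pairwise_alignment")
  }
  out
}

#' Weighted edit distance between two sequences
#'
#' The minimum alignment cost over all pair-wise alignments of `a` and `b`
#' under the cost model, by full-matrix dynamic programming in `O(NM)`
#' time. With `traceback = TRUE` one optimal alignment is returned;
#' tie-breaking is deterministic (diagonal, then deletion from `a`, then
#' insertion).
#'
#' @param a,b Sequences as strings (no gap characters).
#' @param costs A [cost_model()].
#' @param traceback Return an optimal alignment as well?
#' @param case_fold Fold input to lower case (default `TRUE`).
#' @return A [dip_distance] object.
#' @examples
#' edit_distance("actgaaa", "ataaaa")$distance   # 2
#' edit_distance("aggcca", "agcgcca")$distance   # 1
#' @export
edit_distance <- function(a, b, costs = cost_model(), traceback = FALSE,
                          case_fold = TRUE) {
  stopifnot(inherits(costs, "cost_model"))
  edit_dp(a, b, costs, traceback, banded = FALSE, case_fold = case_fold)
}

#' Banded edit distance with threshold doubling
#'
#' Computes the same value as [edit_distance()] but restricts the dynamic
#' program to diagonals `j - i` within a band around the diagonals
#' connecting the start and end cells. Starting from a threshold `t` (at
#' least the length-difference lower bound `|N - M| * indel`), the band
#' radius is `ceiling(t / (2 * cmin))` where `cmin` is the smallest
#' strictly positive single-column cost; `t` doubles until the computed
#' value is at most `t`, at which point any path leaving the band provably
#' costs more than the value found and the result is exact. Runtime is
#' `O(N * D)` for distance `D` under unit costs.
#'
#' @inheritParams edit_distance
#' @return A [dip_distance] object.
#' @examples
#' banded_edit_distance("actgaaa", "ataaaa")$distance  # 2
#' @export
banded_edit_distance <- function(a, b, costs = cost_model(),
                                 traceback = FALSE, case_fold = TRUE) {
  stopifnot(inherits(costs, "cost_model"))
  edit_dp(a, b, costs, traceback, banded = TRUE, case_fold = case_fold)
}
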