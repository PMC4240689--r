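#' Pair-of-haploids-to-diploid distance (cubic DP)
#'
#' Distance between a diploid, given as the pair-wise alignment of its two
#' haplotypes, and a pair of haploid sequences `x`, `y`: the minimum over
#' all recombinations (column-wise row exchanges) of the diploid's
#' alignment of `D(A', x) + D(B', y)`, where `A'`, `B'` are the recombined
#' haplotypes and `D` is the weighted edit distance. Computed by a dynamic
#' program over cells `(i, j, k)` — prefixes of `x`, of `y` and of the
#' alignment columns — in `O(N * M * L)` time. Each consumed alignment
#' column may be used in its original or swapped orientation, which is what
#' lets the measure ignore phasing switch errors.
#'
#' With `traceback = TRUE` the result carries one optimal recombination
#' mask (bit 1 = column kept), its switch positions, the recombined
#' alignment, and the two optimal output alignments (`A'` vs `x`, `B'` vs
#' `y`). Orientation ties (columns whose two symbols are equal) inherit the
#' nearest decided orientation so that spurious switches are not reported.
#'
#' @param aln A [pairwise_alignment()] representing the diploid.
#' @param x,y Haploid sequences as strings (no gaps).
#' @param costs A [cost_model()].
#' @param traceback Also reconstruct mask and alignments? (Distance-only
#'   mode uses two DP planes and handles thousands of positions; traceback
#'   stores the full backpointer cube and is meant for moderate sizes.)
#' @param case_fold Fold input to lower case (default `TRUE`).
#' @return A [dip_distance] object.
#' @examples
#' aln <- pairwise_alignment("tc", "ag")
#' hap2dip_distance(aln, "ngc", "atv", cost_model(mismatch = 10))$distance  # 6
#' @export
hap2dip_distance <- function(aln, x, y, costs = cost_model(),
                             traceback = FALSE, case_fold = TRUE) {
  stopifnot(inherits(aln, "pairwise_alignment"), inherits(costs, "cost_model"))
  ok <- validate_alignment(aln)
  if (!ok) stop("invalid diploid alignment: ", attr(ok, "diagnostics"))
  x <- norm_seq(x, case_fold); y <- norm_seq(y, case_fold)
  if (grepl(GAP, x, fixed = TRUE) || grepl(GAP, y, fixed = TRUE))
    stop("haploid sequences must not contain the gap symbol '-'")
  syms <- observed_symbols(c(x, y, aln$top, aln$bottom))
  enc <- encode_strings(c(x, y, aln$top, aln$bottom), syms)
  cm <- cost_matrix_for(costs, syms)
  raw <- cpp_hap2dip(enc[[1L]], enc[[2L]], enc[[3L]], enc[[4L]], cm, traceback)
  out <- new_dip_distance(raw$distance, "hap2dip",
                          diploid = aln, x = x, y = y)
  if (traceback) {
    out$mask <- as.integer(raw$mask)
    out$switch_positions <- switch_positions(out$mask)
    out$recombined <- apply_recombination(aln, out$mask)
    out$alignment_ax <- decode_alignment(raw$aln1_top, raw$aln1_bottom, syms)
    out$alignment_by <- decode_alignment(raw$aln2_top, raw$aln2_bottom, syms)
  }
  out
}

# Decode a traceback alignment from integer rows, dropping all-gap columns
# (artifacts of gap-bearing diploid columns aligned against nothing).
decode_alignment <- function(top, bottom, syms) {
  keep <- !(top == 0L & bottom == 0L)
  top <- top[keep]; bottom <- bottom[keep]
  if (length(top) == 0L)
    return(structure(list(top = "", bottom = "", length = 0L),
                     class = "pairwise_alignment"))
  pairwise_alignment(decode_ints(top, syms), decode_ints(bottom, syms),
                     case_fold = FALSE)
}

#' Report on a traceback-enabled distance result
#'
#' Collects the phasing-relevant quantities of a [hap2dip_distance()] (or
#' [sync_distance()]) result computed with `traceback = TRUE` into a plain
#' list: distance, mask, 1-based switch positions, the recombined haplotype
#' sequences and the optimal output alignments. Errors if the result holds
#' no traceback.
#'
#' @param result A [dip_distance] with traceback fields.
#' @return A named list.
#' @export
hap2dip_report <- function(result) {
  stopifnot(inherits(result, "dip_distance"))
  if (is.null(result$mask))
    stop("result carries no traceback; recompute with traceback = TRUE")
  list(algorithm = result$algorithm,
       distance = result$distance,
       mask = result$mask,
       switch_positions = result$switch_positions,
       a_prime = strip_gaps(result$recombined$top),
       b_prime = strip_gaps(result$recombined$bottom),
       alignment_ax = result$alignment_ax,
       alignment_by = result$alignment_by)
}
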