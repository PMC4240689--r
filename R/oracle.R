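#' Brute-force one-sided distance by mask enumeration
#'
#' Exhaustive reference for [hap2dip_distance()]: enumerates all `2^L`
#' recombination masks of the diploid alignment, strips the gaps of each
#' recombinant and sums the two edit distances to `x` and `y`. Exponential
#' — intended as an oracle on small instances; refuses alignments longer
#' than `max_length` columns.
#'
#' Masks are enumerated in canonical numeric order (column 1 is the least
#' significant bit), so ties resolve to the lowest mask value and the
#' reported optimal mask is reproducible.
#'
#' @param aln A [pairwise_alignment()] (the diploid).
#' @param x,y Haploid sequences as strings.
#' @param costs A [cost_model()].
#' @param max_length Refuse instances with more alignment columns than
#'   this (default 16).
#' @param case_fold Fold input to lower case.
#' @return A [dip_distance] with the optimal `mask`.
#' @examples
#' aln <- pairwise_alignment("tc", "ag")
#' brute_force_one_sided(aln, "ngc", "atv", cost_model(mismatch = 10))
#' @export
brute_force_one_sided <- function(aln, x, y, costs = cost_model(),
                                  max_length = 16L, case_fold = TRUE) {
  stopifnot(inherits(aln, "pairwise_alignment"), inherits(costs, "cost_model"))
  if (aln$length > max_length)
    stop("alignment has ", aln$length, " columns; brute force is capped at ",
         max_length, " (raise max_length deliberately to override)")
  x <- norm_seq(x, case_fold); y <- norm_seq(y, case_fold)
  best <- Inf; best_mask <- NULL
  for (m in 0:(2^aln$length - 1L)) {
    mask <- mask_from_int(m, aln$length)
    rec <- apply_recombination(aln, mask)
    d <- edit_distance(strip_gaps(rec$top), x, costs)$distance +
         edit_distance(strip_gaps(rec$bottom), y, costs)$distance
    if (d < best) { best <- d; best_mask <- mask }
  }
  new_dip_distance(best, "brute_force_one_sided", mask = best_mask)
}

#' Brute-force two-sided diploid-to-diploid distance
#'
#' The general diploid-to-diploid distance: minimum over recombinations of
#' *both* alignments of `D(A', X') + D(B', Y')`. No efficient algorithm is
#' known for this problem, so it is provided only as an exhaustive
#' enumeration over all `2^(L1 + L2)` mask pairs, capped at `max_bits`
#' total mask bits. The definition is symmetric in the two diploids.
#'
#' @param aln1,aln2 Two [pairwise_alignment()] objects.
#' @param costs A [cost_model()].
#' @param max_bits Refuse instances with `L1 + L2` above this (default 24).
#' @return A [dip_distance] with optimal `mask1`, `mask2` and their switch
#'   positions.
#' @examples
#' d <- brute_force_two_sided(pairwise_alignment("tc", "ag"),
#'                            pairwise_alignment("ngc", "atv"),
#'                            cost_model(mismatch = 10))
#' d$distance  # 2
#' @export
brute_force_two_sided <- function(aln1, aln2, costs = cost_model(),
                                  max_bits = 24L) {
  stopifnot(inherits(aln1, "pairwise_alignment"),
            inherits(aln2, "pairwise_alignment"),
            inherits(costs, "cost_model"))
  bits <- aln1$length + aln2$length
  if (bits > max_bits)
    stop("mask pair needs ", bits, " bits; brute force is capped at ",
         max_bits, " (raise max_bits deliberately to override)")
  rec1 <- lapply(0:(2^aln1$length - 1L), function(m) {
    r <- apply_recombination(aln1, mask_from_int(m, aln1$length))
    list(a = strip_gaps(r$top), b = strip_gaps(r$bottom))
  })
  rec2 <- lapply(0:(2^aln2$length - 1L), function(m) {
    r <- apply_recombination(aln2, mask_from_int(m, aln2$length))
    list(x = strip_gaps(r$top), y = strip_gaps(r$bottom))
  })
  best <- Inf; bm1 <- NULL; bm2 <- NULL
  for (m1 in seq_along(rec1)) {
    for (m2 in seq_along(rec2)) {
      d <- edit_distance(rec1[[m1]]$a, rec2[[m2]]$x, costs)$distance +
           edit_distance(rec1[[m1]]$b, rec2[[m2]]$y, costs)$distance
      if (d < best) { best <- d; bm1 <- m1 - 1L; bm2 <- m2 - 1L }
    }
  }
  mask1 <- mask_from_int(bm1, aln1$length)
  mask2 <- mask_from_int(bm2, aln2$length)
  res <- new_dip_distance(best, "brute_force_two_sided",
                          mask1 = mask1, mask2 = mask2)
  res$switch_positions1 <- switch_positions(mask1)
  res$switch_positions2 <- switch_positions(mask2)
  res
}

# Mask bits of the integer m over L columns; column 1 = least significant
# bit, so canonical numeric order on m gives reproducible tie-breaking.
mask_from_int <- function(m, L) {
  if (L == 0L) return(integer(0))
  as.integer(bitwAnd(bitwShiftR(as.integer(m), 0:(L - 1L)), 1L))
}
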