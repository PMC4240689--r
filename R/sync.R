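#' Guiding function of a pair-wise alignment
#'
#' An equivalent encoding of an alignment `(S^X, S^Y)` of sequences `x` and
#' `y`: for every column prefix length `z`, `h_i(z)` and `h_j(z)` are the
#' numbers of non-gap symbols of the top and bottom row consumed so far
#' (`h_i(z) = z - #gaps in S^X[1..z]`, and likewise for `h_j`). Both arrays
#' start at 0, are nondecreasing with steps in `{0, 1}`, and at least one
#' advances per column because no column holds two gaps. The alignment is
#' reconstructible from `(x, y, h)`; see the `alignment` element returned
#' by [guiding_to_alignment()].
#'
#' @param aln A [pairwise_alignment()].
#' @return An object of class `guiding_function`: list with integer arrays
#'   `h_i`, `h_j` (indexed `0..L`, i.e. element `z + 1` is `h(z)`), and the
#'   gap-free sequences `x`, `y`.
#' @examples
#' h <- guiding_function(pairwise_alignment("actg---g", "a-tgagag"))
#' h$h_i[2 + 1]  # h_i(2) = 2
#' h$h_j[2 + 1]  # h_j(2) = 1
#' @export
guiding_function <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ok <- validate_alignment(aln)
  if (!ok) stop("invalid alignment: ", attr(ok, "diagnostics"))
  t <- chars(aln$top); b <- chars(aln$bottom)
  structure(list(h_i = c(0L, cumsum(t != GAP)),
                 h_j = c(0L, cumsum(b != GAP)),
                 x = strip_gaps(aln$top), y = strip_gaps(aln$bottom),
                 length = aln$length),
            class = "guiding_function")
}

#' @export
print.guiding_function <- function(x, ...) {
  cat("<guiding_function> over", x$length, "columns; |x| =", nchar(x$x),
      " |y| =", nchar(x$y), "\n")
  invisible(x)
}

#' Reconstruct the alignment encoded by a guiding function
#'
#' @param h A [guiding_function()].
#' @return The [pairwise_alignment()] it encodes.
#' @export
guiding_to_alignment <- function(h) {
  stopifnot(inherits(h, "guiding_function"))
  xc <- chars(h$x); yc <- chars(h$y)
  di <- diff(h$h_i); dj <- diff(h$h_j)
  top <- rep(GAP, h$length); bottom <- rep(GAP, h$length)
  top[di == 1L] <- xc[h$h_i[-1L][di == 1L]]
  bottom[dj == 1L] <- yc[h$h_j[-1L][dj == 1L]]
  pairwise_alignment(paste(top, collapse = ""), paste(bottom, collapse = ""),
                     case_fold = FALSE)
}

#' Transition cost of the synchronized DP
#'
#' The step-cost function of the synchronized diploid-to-diploid dynamic
#' program. A step is described by the previous and current index triples
#' `(i, j, k)`: `i`, `j` are the numbers of guide haplotype symbols
#' consumed (as given by the guiding function), `k` the number of diploid
#' alignment columns consumed. Legal steps advance `k` by 0 or 1 and
#' `(i, j)` by `(1,1)`, `(0,1)`, `(1,0)` or — only if `k` advances —
#' `(0,0)`. Where a diploid column is consumed the cost is minimized over
#' its two orientations (original and swapped rows).
#'
#' @param prev,cur Integer triples `c(i, j, k)`.
#' @param a,b Symbols of the consumed diploid alignment column (may be
#'   `'-'`); required iff the step advances `k`.
#' @param x,y Consumed guide haplotype symbols; required iff the step
#'   advances `i` resp. `j`.
#' @param costs A [cost_model()].
#' @return Numeric step cost.
#' @examples
#' zeta(c(0, 0, 0), c(0, 0, 1), a = "g", b = "-")           # 1: gap column
#' zeta(c(0, 0, 0), c(1, 1, 0), x = "a", y = "c")           # 2: two deletions
#' @export
zeta <- function(prev, cur, a = NULL, b = NULL, x = NULL, y = NULL,
                 costs = cost_model()) {
  stopifnot(length(prev) == 3L, length(cur) == 3L,
            inherits(costs, "cost_model"))
  d <- as.integer(cur) - as.integer(prev)
  di <- d[1L]; dj <- d[2L]; dk <- d[3L]
  legal <- (dk %in% 0:1) && ((di == 1L && dj == 1L) || (di == 0L && dj == 1L) ||
           (di == 1L && dj == 0L) || (di == 0L && dj == 0L && dk == 1L))
  if (!legal)
    stop("illegal synchronized step: delta = (", di, ", ", dj, ", ", dk, ")")
  if (dk == 1L) {
    if (is.null(a) || is.null(b))
      stop("steps consuming a diploid column need its symbols a and b")
    xs <- if (di == 1L) x else GAP
    ys <- if (dj == 1L) y else GAP
    if (di == 1L && is.null(x) || dj == 1L && is.null(y))
      stop("steps consuming guide symbols need them supplied")
    straight <- column_cost(costs, xs, a) + column_cost(costs, ys, b)
    crossed <- column_cost(costs, xs, b) + column_cost(costs, ys, a)
    min(straight, crossed)
  } else {
    (if (di == 1L) {
       if (is.null(x)) stop("step consuming a guide symbol needs it supplied")
       column_cost(costs, x, GAP)
     } else 0) +
    (if (dj == 1L) {
       if (is.null(y)) stop("step consuming a guide symbol needs it supplied")
       column_cost(costs, y, GAP)
     } else 0)
  }
}

sync_front_end <- function(aln_ab, aln_xy, costs) {
  stopifnot(inherits(aln_ab, "pairwise_alignment"),
            inherits(aln_xy, "pairwise_alignment"),
            inherits(costs, "cost_model"))
  for (nm in list(list(aln_ab, "diploid"), list(aln_xy, "guide"))) {
    ok <- validate_alignment(nm[[1L]])
    if (!ok) stop("invalid ", nm[[2L]], " alignment: ", attr(ok, "diagnostics"))
  }
  h <- guiding_function(aln_xy)
  syms <- observed_symbols(c(h$x, h$y, aln_ab$top, aln_ab$bottom))
  enc <- encode_strings(c(h$x, h$y, aln_ab$top, aln_ab$bottom), syms)
  list(h = h, syms = syms, enc = enc, cm = cost_matrix_for(costs, syms))
}

#' Synchronized diploid-to-diploid distance (quadratic DP)
#'
#' Distance between two diploids, each given as a pair-wise alignment of
#' its haplotypes. The first alignment (`aln_ab`) may recombine freely
#' column by column; the second (`aln_xy`) acts as the guide: its own
#' alignment of `x` and `y` is kept fixed, and the two output alignments
#' (`A'` vs `x`, `B'` vs `y`) must advance in lockstep with it, as encoded
#' by its guiding function. This synchronization restricts the search
#' space of the pair-of-haploids-to-diploid problem (so the value is never
#' smaller than [hap2dip_distance()] on `x`, `y`), but shrinks the DP to
#' `O(L1 * L2)` cells over guide columns times diploid columns.
#'
#' The measure is directional: `sync_distance(a, b)` recombines `a` against
#' guide `b` and need not equal `sync_distance(b, a)`; take the minimum of
#' both calls for a symmetric summary.
#'
#' A nonzero `costs$penalty` charges each orientation change between
#' consecutive consumed diploid columns; orientation then becomes a second
#' DP state bit. With penalty 0 orientation is a free per-column choice.
#'
#' @param aln_ab The diploid allowed to recombine.
#' @param aln_xy The guide diploid (its alignment is kept fixed).
#' @param costs A [cost_model()]; `costs$penalty` is the per-switch
#'   recombination penalty.
#' @param traceback Also reconstruct the orientation mask over `aln_ab`
#'   columns, the recombined alignment, and the two output alignments?
#' @param keep_table Also return the full DP value table (rows `z = 0..L1`,
#'   columns `k = 0..L2`), e.g. for [check_monotonicity()].
#' @return A [dip_distance] object.
#' @examples
#' a <- pairwise_alignment("tc", "ag")
#' b <- pairwise_alignment("ngc", "atv")
#' sync_distance(a, b, cost_model(mismatch = 10))$distance
#' @export
sync_distance <- function(aln_ab, aln_xy, costs = cost_model(),
                          traceback = FALSE, keep_table = FALSE) {
  fe <- sync_front_end(aln_ab, aln_xy, costs)
  raw <- cpp_sync_full(fe$enc[[1L]], fe$enc[[2L]], fe$h$h_i, fe$h$h_j,
                       fe$enc[[3L]], fe$enc[[4L]], fe$cm, costs$penalty,
                       traceback, keep_table)
  out <- new_dip_distance(raw$distance, "sync")
  if (keep_table) out$table <- raw$table
  if (traceback) {
    out$mask <- as.integer(raw$mask)
    out$switch_positions <- switch_positions(out$mask)
    out$recombined <- apply_recombination(aln_ab, out$mask)
    out$alignment_ax <- decode_alignment(raw$aln1_top, raw$aln1_bottom, fe$syms)
    out$alignment_by <- decode_alignment(raw$aln2_top, raw$aln2_bottom, fe$syms)
  }
  out
}

#' Banded synchronized distance with threshold doubling
#'
#' Same value as [sync_distance()], restricted to diagonals `z - k` within
#' a doubling band. The pruning is justified by the strict monotonicity of
#' the synchronized DP table (see [check_monotonicity()]): every step that
#' advances only `z` or only `k` has strictly positive cost, because the
#' guide haplotypes contain no gaps and no diploid column holds two gaps.
#' Runtime is `O(L * D)` for distance `D` under unit costs.
#'
#' @inheritParams sync_distance
#' @return A [dip_distance] object (distance only).
#' @export
sync_distance_banded <- function(aln_ab, aln_xy, costs = cost_model()) {
  fe <- sync_front_end(aln_ab, aln_xy, costs)
  cmin <- min_positive_cost(fe$cm)
  t0 <- max(cmin, abs(fe$h$length - aln_ab$length) * costs$indel)
  raw <- cpp_sync_banded(fe$enc[[1L]], fe$enc[[2L]], fe$h$h_i, fe$h$h_j,
                         fe$enc[[3L]], fe$enc[[4L]], fe$cm, costs$penalty,
                         t0, cmin)
  new_dip_distance(raw$distance, "sync_banded", threshold = raw$threshold)
}

#' Strict monotonicity of a synchronized DP table
#'
#' Checks that every cell strictly exceeds its upper and left neighbors,
#' the property that justifies the banded variant: under a valid cost model
#' (positive indel, no double-gap columns, gap-free guide haplotypes) it
#' holds for every instance.
#'
#' @param table Numeric matrix as returned in the `table` element of
#'   [sync_distance()] with `keep_table = TRUE`.
#' @return `TRUE` iff strictly increasing along both rows and columns.
#' @export
check_monotonicity <- function(table) {
  stopifnot(is.matrix(table), is.numeric(table))
  rows_ok <- nrow(table) < 2L || all(diff(table) > 0)
  cols_ok <- ncol(table) < 2L || all(t(diff(t(table))) > 0)
  isTRUE(rows_ok && cols_ok)
}
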