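# Independent reference implementations used as oracles. Both are written
# straight from the definitions (plain R, full matrices, no banding, no
# shared code with the package kernels) and are only ever run on small
# instances.

ref_edit_distance <- function(a, b, costs = cost_model()) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  D <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) D[i + 1L, 1L] <- D[i, 1L] + column_cost(costs, A[i], "-")
  for (j in seq_len(m)) D[1L, j + 1L] <- D[1L, j] + column_cost(costs, "-", B[j])
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j] + column_cost(costs, A[i], B[j]),
        D[i, j + 1L] + column_cost(costs, A[i], "-"),
        D[i + 1L, j] + column_cost(costs, "-", B[j]))
    }
  }
  D[n + 1L, m + 1L]
}

# Straightforward full-table synchronized DP: guide columns z, diploid
# columns k, per-column orientation minimum (free recombination). With
# `crossed_allowed = FALSE` every consumed diploid column keeps its
# original orientation, which is the no-switch (infinite penalty) limit.
ref_sync_distance <- function(aln_ab, aln_xy, costs = cost_model(),
                              crossed_allowed = TRUE) {
  sx <- strsplit(aln_xy$top, "")[[1L]]; sy <- strsplit(aln_xy$bottom, "")[[1L]]
  X <- sx[sx != "-"]; Y <- sy[sy != "-"]
  hi <- c(0L, cumsum(sx != "-")); hj <- c(0L, cumsum(sy != "-"))
  A <- strsplit(aln_ab$top, "")[[1L]]; B <- strsplit(aln_ab$bottom, "")[[1L]]
  L1 <- length(sx); L2 <- length(A)
  D <- matrix(Inf, L1 + 1L, L2 + 1L)
  D[1L, 1L] <- 0
  for (z in 0:L1) {
    for (k in 0:L2) {
      if (z == 0L && k == 0L) next
      cand <- numeric(0)
      if (z > 0L) {
        xs <- if (hi[z + 1L] > hi[z]) X[hi[z + 1L]] else "-"
        ys <- if (hj[z + 1L] > hj[z]) Y[hj[z + 1L]] else "-"
        if (k > 0L) {
          straight <- column_cost(costs, xs, A[k]) + column_cost(costs, ys, B[k])
          crossed <- column_cost(costs, xs, B[k]) + column_cost(costs, ys, A[k])
          dg <- if (crossed_allowed) min(straight, crossed) else straight
          cand <- c(cand, D[z, k] + dg)
        }
        zc <- (if (xs != "-") column_cost(costs, xs, "-") else 0) +
              (if (ys != "-") column_cost(costs, ys, "-") else 0)
        cand <- c(cand, D[z, k + 1L] + zc)
      }
      if (k > 0L) {
        cand <- c(cand, D[z + 1L, k] + column_cost(costs, "-", A[k]) +
                          column_cost(costs, "-", B[k]))
      }
      D[z + 1L, k + 1L] <- min(cand)
    }
  }
  D[L1 + 1L, L2 + 1L]
}

swap_rows <- function(aln) {
  pairwise_alignment(aln$bottom, aln$top, case_fold = FALSE)
}
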