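# Random instance generators shared by the test files.

DNA <- c("a", "c", "g", "t")

rand_seq <- function(n, alpha = DNA) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# Random valid pair-wise alignment: per-row gap probability, double-gap
# columns repaired by resampling the bottom symbol.
rand_aln <- function(L, gap_p = 0.15, alpha = DNA) {
  top <- ifelse(runif(L) < gap_p, "-", sample(alpha, L, replace = TRUE))
  bot <- ifelse(runif(L) < gap_p, "-", sample(alpha, L, replace = TRUE))
  bad <- top == "-" & bot == "-"
  bot[bad] <- sample(alpha, sum(bad), replace = TRUE)
  pairwise_alignment(paste(top, collapse = ""), paste(bot, collapse = ""))
}

# Point-mutate a sequence (substitutions and single-base deletions).
mutate_seq <- function(s, n_sub = 2L, n_del = 1L, alpha = DNA) {
  x <- strsplit(s, "")[[1L]]
  pos <- sample(seq_along(x), min(length(x), n_sub + n_del))
  subs <- pos[seq_len(min(n_sub, length(pos)))]
  for (p in subs) x[p] <- sample(setdiff(alpha, x[p]), 1L)
  dels <- setdiff(pos, subs)
  if (length(dels)) x <- x[-dels]
  paste(x, collapse = "")
}

# A biologically plausible diploid: two mutated copies of a common
# sequence, aligned optimally under unit costs.
rand_diploid <- function(n, n_sub = 2L, n_del = 1L) {
  s <- rand_seq(n)
  banded_edit_distance(mutate_seq(s, n_sub, n_del),
                       mutate_seq(s, n_sub, n_del),
                       traceback = TRUE)$alignment
}

unit_costs <- cost_model()
weighted_costs <- cost_model(mismatch = 10, indel = 1)
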