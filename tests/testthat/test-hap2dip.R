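test_that("the weighted counterexample gives one-sided distance 6", {
  aln <- pairwise_alignment("tc", "ag")
  wc <- cost_model(mismatch = 10, indel = 1)
  expect_equal(hap2dip_distance(aln, "ngc", "atv", wc)$distance, 6)
})

test_that("exact recombinants of the diploid are at distance zero", {
  aln <- pairwise_alignment("ag", "ct")
  r1 <- hap2dip_distance(aln, "ag", "ct", traceback = TRUE)
  expect_equal(r1$distance, 0)
  expect_identical(r1$mask, c(1L, 1L))
  expect_length(r1$switch_positions, 0)

  r0 <- hap2dip_distance(aln, "ct", "ag", traceback = TRUE)
  expect_equal(r0$distance, 0)
  expect_identical(r0$mask, c(0L, 0L))
  expect_length(r0$switch_positions, 0)

  # every recombinant of a random diploid is at distance 0 from it
  set.seed(31)
  for (i in 1:15) {
    aln <- rand_aln(sample(1:10, 1))
    mask <- sample(0:1, aln$length, replace = TRUE)
    rec <- apply_recombination(aln, mask)
    expect_equal(hap2dip_distance(aln, strip_gaps(rec$top),
                                  strip_gaps(rec$bottom))$distance, 0)
  }
})

test_that("cubic DP equals exhaustive mask enumeration on random instances", {
  set.seed(32)
  for (i in 1:60) {
    costs <- if (i %% 2) unit_costs else weighted_costs
    aln <- rand_aln(sample(1:8, 1))
    x <- rand_seq(sample(0:8, 1)); y <- rand_seq(sample(0:8, 1))
    expect_equal(hap2dip_distance(aln, x, y, costs)$distance,
                 brute_force_one_sided(aln, x, y, costs)$distance)
  }
})

test_that("distance is bounded by the two fixed pairings and row-swap invariant", {
  set.seed(33)
  for (i in 1:20) {
    costs <- if (i %% 2) unit_costs else weighted_costs
    aln <- rand_aln(sample(1:9, 1))
    hp <- haplotypes(aln)
    x <- rand_seq(sample(1:9, 1)); y <- rand_seq(sample(1:9, 1))
    d <- hap2dip_distance(aln, x, y, costs)$distance
    fixed <- min(
      edit_distance(hp[["top"]], x, costs)$distance +
        edit_distance(hp[["bottom"]], y, costs)$distance,
      edit_distance(hp[["bottom"]], x, costs)$distance +
        edit_distance(hp[["top"]], y, costs)$distance)
    expect_lte(d, fixed)
    swapped <- pairwise_alignment(aln$bottom, aln$top)
    expect_equal(hap2dip_distance(swapped, x, y, costs)$distance, d)
  }
})

test_that("traceback report is self-consistent", {
  wc <- cost_model(mismatch = 10, indel = 1)
  r <- hap2dip_distance(pairwise_alignment("tc", "ag"), "ngc", "atv", wc,
                        traceback = TRUE)
  rep <- hap2dip_report(r)
  expect_equal(rep$distance, 6)
  # recompute the distance from the reported recombined haplotypes
  expect_equal(edit_distance(rep$a_prime, "ngc", wc)$distance +
                 edit_distance(rep$b_prime, "atv", wc)$distance, 6)
  # and from the reported optimal alignments
  expect_equal(alignment_cost(r$alignment_ax, wc) +
                 alignment_cost(r$alignment_by, wc), 6)
  expect_identical(strip_gaps(r$alignment_ax$bottom), "ngc")
  expect_identical(strip_gaps(r$alignment_by$bottom), "atv")
  expect_identical(strip_gaps(r$alignment_ax$top), rep$a_prime)

  expect_error(hap2dip_report(hap2dip_distance(
    pairwise_alignment("tc", "ag"), "ngc", "atv", wc)), "traceback")

  set.seed(34)
  for (i in 1:15) {
    costs <- if (i %% 2) unit_costs else wc
    aln <- rand_aln(sample(1:8, 1))
    x <- rand_seq(sample(1:8, 1)); y <- rand_seq(sample(1:8, 1))
    r <- hap2dip_distance(aln, x, y, costs, traceback = TRUE)
    expect_equal(alignment_cost(r$alignment_ax, costs) +
                   alignment_cost(r$alignment_by, costs), r$distance)
    expect_identical(strip_gaps(r$recombined$top),
                     strip_gaps(r$alignment_ax$top))
  }
})

test_that("invalid diploid alignments are rejected", {
  aln <- structure(list(top = "a-", bottom = "--", length = 2L),
                   class = "pairwise_alignment")
  expect_error(hap2dip_distance(aln, "a", "a"), "column 2")
  expect_error(hap2dip_distance(pairwise_alignment("ac", "gt"), "a-c", "a"),
               "gap")
})
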