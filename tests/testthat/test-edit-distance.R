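test_that("alignment cost sums the column costs", {
  expect_equal(alignment_cost(pairwise_alignment("ab", "ab")), 0)
  expect_equal(alignment_cost(pairwise_alignment("a-", "ab")), 1)
  # four gap columns at unit cost
  expect_equal(alignment_cost(pairwise_alignment("actg---g", "a-tgagag")), 4)
  wc <- cost_model(mismatch = 10, indel = 1)
  expect_equal(alignment_cost(pairwise_alignment("ac", "tc"), wc), 10)
})

test_that("edit distance reproduces the worked decomposition values", {
  expect_equal(edit_distance("actgaaa", "ataaaa")$distance, 2)
  expect_equal(edit_distance("aggcca", "agcgcca")$distance, 1)
  expect_equal(edit_distance("", "abc")$distance, 3)
  # substitutions 10x the indel: one indel beats any substitution route
  wc <- cost_model(mismatch = 10, indel = 1)
  expect_equal(edit_distance("tc", "ntc", wc)$distance, 1)
  expect_equal(edit_distance("ag", "agv", wc)$distance, 1)
})

test_that("edit distance matches the reference DP and is metric-like", {
  set.seed(21)
  for (i in 1:40) {
    costs <- if (i %% 2) unit_costs else cost_model(mismatch = 2.5, indel = 1.25)
    a <- rand_seq(sample(0:12, 1)); b <- rand_seq(sample(0:12, 1))
    d <- edit_distance(a, b, costs)$distance
    expect_equal(d, ref_edit_distance(a, b, costs))
    expect_equal(d, edit_distance(b, a, costs)$distance)  # symmetry
    expect_equal(edit_distance(a, a, costs)$distance, 0)
    expect_equal(edit_distance(a, "", costs)$distance, nchar(a) * costs$indel)
  }
  # triangle inequality under unit costs
  for (i in 1:30) {
    a <- rand_seq(sample(0:10, 1)); b <- rand_seq(sample(0:10, 1))
    c_ <- rand_seq(sample(0:10, 1))
    expect_lte(edit_distance(a, c_)$distance,
               edit_distance(a, b)$distance + edit_distance(b, c_)$distance)
  }
})

test_that("traceback alignment realizes the reported distance", {
  set.seed(22)
  for (i in 1:25) {
    costs <- if (i %% 2) unit_costs else weighted_costs
    a <- rand_seq(sample(1:15, 1)); b <- rand_seq(sample(1:15, 1))
    for (fun in list(edit_distance, banded_edit_distance)) {
      r <- fun(a, b, costs, traceback = TRUE)
      expect_equal(alignment_cost(r$alignment, costs), r$distance)
      expect_identical(strip_gaps(r$alignment$top), a)
      expect_identical(strip_gaps(r$alignment$bottom), b)
    }
  }
})

test_that("banded distance equals the full matrix on random pairs", {
  expect_equal(banded_edit_distance("actgaaa", "ataaaa")$distance, 2)
  expect_equal(banded_edit_distance("acgt", "acgt", weighted_costs)$distance, 0)
  set.seed(23)
  for (i in 1:60) {
    costs <- if (i %% 2) unit_costs else cost_model(mismatch = 3, indel = 2)
    a <- rand_seq(sample(0:120, 1)); b <- rand_seq(sample(0:120, 1))
    expect_equal(banded_edit_distance(a, b, costs)$distance,
                 edit_distance(a, b, costs)$distance)
  }
  # related pairs exercise small-distance bands
  for (i in 1:20) {
    s <- rand_seq(100)
    a <- mutate_seq(s, 3, 1); b <- mutate_seq(s, 3, 1)
    expect_equal(banded_edit_distance(a, b)$distance,
                 edit_distance(a, b)$distance)
  }
})

test_that("sequences with gap characters are rejected", {
  expect_error(edit_distance("a-c", "ac"), "gap")
})
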