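test_that("guiding function encodes and round-trips an alignment", {
  aln <- pairwise_alignment("actg---g", "a-tgagag")
  h <- guiding_function(aln)
  expect_equal(c(h$h_i[1], h$h_j[1]), c(0, 0))          # h(0)
  expect_equal(c(h$h_i[3], h$h_j[3]), c(2, 1))          # h(2)
  expect_equal(c(h$h_i[9], h$h_j[9]), c(5, 7))          # h(8) = (8-3, 8-1)
  expect_equal(h$h_i[9], nchar(h$x))
  expect_equal(h$h_j[9], nchar(h$y))
  back <- guiding_to_alignment(h)
  expect_identical(back$top, aln$top)
  expect_identical(back$bottom, aln$bottom)

  set.seed(41)
  for (i in 1:20) {
    aln <- rand_aln(sample(1:15, 1))
    h <- guiding_function(aln)
    steps <- cbind(diff(h$h_i), diff(h$h_j))
    expect_true(all(steps %in% 0:1))
    expect_true(all(rowSums(steps) >= 1))               # no double-gap column
    back <- guiding_to_alignment(h)
    expect_identical(c(back$top, back$bottom), c(aln$top, aln$bottom))
  }
})

test_that("zeta returns orientation-minimized step costs and rejects bad steps", {
  # gap-bearing diploid column consumed alone
  expect_equal(zeta(c(0, 0, 0), c(0, 0, 1), a = "g", b = "-"), 1)
  # both guide haplotypes deleted
  expect_equal(zeta(c(1, 1, 0), c(2, 2, 0), x = "a", y = "c"), 2)
  # matching in straight orientation
  expect_equal(zeta(c(0, 0, 0), c(1, 1, 1), a = "t", b = "g", x = "t", y = "g"), 0)
  # matching in crossed orientation costs the same
  expect_equal(zeta(c(0, 0, 0), c(1, 1, 1), a = "t", b = "g", x = "g", y = "t"), 0)
  wc <- cost_model(mismatch = 10, indel = 1)
  expect_equal(zeta(c(0, 0, 0), c(1, 1, 1), a = "t", b = "g", x = "t", y = "c",
                    costs = wc), 10)  # straight orientation keeps the t match
  expect_error(zeta(c(0, 0, 0), c(2, 1, 1), a = "t", b = "g", x = "t", y = "g"),
               "illegal")
  expect_error(zeta(c(0, 0, 0), c(0, 0, 0)), "illegal")
  expect_error(zeta(c(0, 0, 0), c(0, 0, 1)), "symbols")
})

test_that("synchronized distance of an alignment with itself is zero", {
  set.seed(42)
  for (i in 1:15) {
    aln <- rand_aln(sample(1:20, 1))
    expect_equal(sync_distance(aln, aln)$distance, 0)
    expect_equal(sync_distance_banded(aln, aln)$distance, 0)
  }
})

test_that("sync DP matches an independent full-table reference", {
  wc <- cost_model(mismatch = 10, indel = 1)
  a <- pairwise_alignment("tc", "ag")
  g <- pairwise_alignment("ngc", "atv")
  d <- sync_distance(a, g, wc)$distance
  expect_equal(d, ref_sync_distance(a, g, wc))
  # synchronization restricts the one-sided search space
  expect_gte(d, hap2dip_distance(a, "ngc", "atv", wc)$distance)

  set.seed(43)
  for (i in 1:40) {
    costs <- if (i %% 2) unit_costs else cost_model(mismatch = 3, indel = 2)
    a <- rand_aln(sample(1:9, 1)); g <- rand_aln(sample(1:9, 1))
    expect_equal(sync_distance(a, g, costs)$distance,
                 ref_sync_distance(a, g, costs))
  }
})

test_that("sync is lower-bounded by the one-sided distance", {
  set.seed(44)
  for (i in 1:25) {
    costs <- if (i %% 2) unit_costs else weighted_costs
    a <- rand_aln(sample(1:8, 1)); g <- rand_aln(sample(1:8, 1))
    hg <- haplotypes(g)
    expect_gte(sync_distance(a, g, costs)$distance,
               hap2dip_distance(a, hg[["top"]], hg[["bottom"]], costs)$distance)
  }
})

test_that("sync traceback realizes the distance and reports the mask", {
  set.seed(45)
  for (i in 1:20) {
    costs <- if (i %% 2) unit_costs else weighted_costs
    a <- rand_aln(sample(1:10, 1)); g <- rand_aln(sample(1:10, 1))
    r <- sync_distance(a, g, costs, traceback = TRUE)
    expect_equal(alignment_cost(r$alignment_ax, costs) +
                   alignment_cost(r$alignment_by, costs), r$distance)
    hg <- haplotypes(g)
    expect_identical(strip_gaps(r$alignment_ax$bottom), hg[["top"]])
    expect_identical(strip_gaps(r$alignment_by$bottom), hg[["bottom"]])
    expect_identical(strip_gaps(r$alignment_ax$top),
                     strip_gaps(r$recombined$top))
    expect_length(r$mask, a$length)
  }
})

test_that("banded sync equals the full matrix", {
  set.seed(46)
  for (i in 1:40) {
    costs <- if (i %% 2) unit_costs else cost_model(mismatch = 3, indel = 2)
    a <- rand_aln(sample(1:30, 1)); g <- rand_aln(sample(1:30, 1))
    expect_equal(sync_distance_banded(a, g, costs)$distance,
                 sync_distance(a, g, costs)$distance)
  }
  # related diploids with small distances exercise narrow bands
  for (i in 1:10) {
    a <- rand_diploid(120); g <- rand_diploid(120)
    expect_equal(sync_distance_banded(a, g)$distance,
                 sync_distance(a, g)$distance)
  }
})

test_that("recombination penalty is monotone and bounded by no-switch costs", {
  set.seed(47)
  for (i in 1:15) {
    a <- rand_aln(sample(2:8, 1)); g <- rand_aln(sample(2:8, 1))
    free <- sync_distance(a, g)$distance
    prev <- free
    for (p in c(0.5, 2, 8)) {
      cp <- cost_model(penalty = p)
      d <- sync_distance(a, g, cp)$distance
      expect_gte(d, prev - 1e-9)
      expect_equal(sync_distance_banded(a, g, cp)$distance, d)
      prev <- d
    }
    # infinite-penalty limit: best single orientation throughout
    no_switch <- min(ref_sync_distance(a, g, crossed_allowed = FALSE),
                     ref_sync_distance(swap_rows(a), g, crossed_allowed = FALSE))
    huge <- sync_distance(a, g, cost_model(penalty = 1e6))$distance
    expect_equal(huge, no_switch)
    expect_gte(no_switch, free - 1e-9)
  }
})

test_that("penalized traceback charges exactly the reported switches", {
  set.seed(48)
  for (i in 1:10) {
    a <- rand_aln(sample(2:8, 1)); g <- rand_aln(sample(2:8, 1))
    cp <- cost_model(penalty = 0.75)
    r <- sync_distance(a, g, cp, traceback = TRUE)
    base <- alignment_cost(r$alignment_ax, cp) + alignment_cost(r$alignment_by, cp)
    # switches counted between consecutive consumed diploid columns
    expect_equal(r$distance, base + 0.75 * length(r$switch_positions))
  }
})

test_that("strict row/column table monotonicity fails on near-identical diploids", {
  # The banded variant rests on strictly positive z-only / k-only step
  # costs, visible in the strictly increasing boundary row and column and
  # in the diagonal-offset lower bound. Full row/column monotonicity of
  # the table cannot hold in general: for identical diploids the final
  # cell is 0 while the boundary cells are positive.
  aln <- pairwise_alignment("ac", "gt")
  tab <- sync_distance(aln, aln, keep_table = TRUE)$table
  expect_equal(tab[nrow(tab), ncol(tab)], 0)
  expect_false(check_monotonicity(tab))

  set.seed(49)
  for (i in 1:20) {
    a <- rand_aln(sample(1:12, 1)); g <- rand_aln(sample(1:12, 1))
    tab <- sync_distance(a, g, keep_table = TRUE)$table
    expect_true(all(diff(tab[, 1]) > 0))   # boundary column
    expect_true(all(diff(tab[1, ]) > 0))   # boundary row
    off <- abs(outer(0:(nrow(tab) - 1L), 0:(ncol(tab) - 1L), "-"))
    expect_true(all(tab >= off - 1e-9))    # >= cmin * |z - k| at unit costs
  }

  # negative control: a corrupted table is flagged
  good <- matrix(c(0, 1, 2, 1, 2, 3, 2, 3, 4), 3, 3)
  expect_true(check_monotonicity(good))
  bad <- good; bad[2, 2] <- 0
  expect_false(check_monotonicity(bad))
})
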