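test_that("configuration is validated", {
  expect_error(sim_config(variant_rate = 1.5), "rates")
  expect_error(sim_config(block_size = 0), "block_size")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("records are deterministic under a fixed seed", {
  for (fun in list(simulate_table1_pair, simulate_table2_pair)) {
    cfg <- sim_config(length = 800L, seed = 99L, mutations = 5L)
    r1 <- fun(cfg); r2 <- fun(cfg)
    expect_identical(r1$reference, r2$reference)
    expect_identical(r1$haplotypes, r2$haplotypes)
    expect_identical(r1$events, r2$events)
    r3 <- fun(sim_config(length = 800L, seed = 100L, mutations = 5L))
    expect_false(identical(r1$haplotypes, r3$haplotypes))
  }
})

test_that("zero mutation settings give identical diploids at distance zero", {
  cfg <- sim_config(length = 400L, mutation_rate = 0, seed = 7L)
  r <- simulate_table1_pair(cfg)
  expect_identical(r$haplotypes$d1_a, r$reference)
  expect_identical(r$haplotypes$d2_b, r$reference)
  expect_equal(sync_distance_banded(r$diploid1, r$diploid2)$distance, 0)
  expect_equal(r$n_mutations, 0L)

  cfg2 <- sim_config(length = 2000L, variant_rate = 0.01, mutations = 0L,
                     seed = 8L)
  r2 <- simulate_table2_pair(cfg2)
  expect_equal(r2$n_mutations, 0L)
  expect_equal(sync_distance_banded(r2$diploid1, r2$diploid2)$distance, 0)
})

test_that("recorded events reproduce the emitted haplotypes exactly", {
  reapply <- function(reference, ev) {
    x <- strsplit(reference, "")[[1L]]
    subs <- ev[ev$type == "snp", , drop = FALSE]
    x[subs$pos] <- subs$alt
    dels <- ev$pos[ev$type == "del"]
    if (length(dels)) x <- x[-dels]
    paste(x, collapse = "")
  }
  r1 <- simulate_table1_pair(sim_config(length = 600L, seed = 12L))
  for (s in names(r1$haplotypes))
    expect_identical(reapply(r1$reference, r1$events[[s]]), r1$haplotypes[[s]])
  r2 <- simulate_table2_pair(sim_config(length = 3000L, seed = 13L,
                                        mutations = 8L))
  for (s in names(r2$haplotypes))
    expect_identical(reapply(r2$reference, r2$events[[s]]), r2$haplotypes[[s]])
  # planted mutation bookkeeping
  expect_equal(r2$n_mutations, nrow(r2$mutations))
  expect_equal(r2$n_mutations, 8L)
})

test_that("mutated copies give agreeing cubic and synchronized distances", {
  r <- simulate_table1_pair(sim_config(length = 300L, seed = 21L))
  h2 <- haplotypes(r$diploid2)
  cubic <- hap2dip_distance(r$diploid1, h2[["top"]], h2[["bottom"]])$distance
  syn <- min(sync_distance(r$diploid1, r$diploid2)$distance,
             sync_distance(r$diploid2, r$diploid1)$distance)
  expect_gte(syn, cubic)        # synchronization can only restrict
  expect_gt(cubic, 0)           # mutations were planted
  # both distances are in the ballpark of the planted mutation count
  expect_lte(cubic, r$n_mutations)
  expect_lte(syn, 2 * r$n_mutations)
})

test_that("planted substitutions are recovered exactly by the sync distance", {
  recovered <- 0L
  for (s in 1:6) {
    r <- simulate_table2_pair(sim_config(length = 4000L, variant_rate = 0.01,
                                         mutations = 10L, block_size = 200L,
                                         seed = 500L + s))
    d <- sync_distance_banded(r$diploid1, r$diploid2)$distance
    if (d == r$n_mutations) recovered <- recovered + 1L
    # the naive fixed-pairing Levenshtein overcounts phase switches
    h <- r$haplotypes
    lev <- min(
      banded_edit_distance(h$d1_a, h$d2_a)$distance +
        banded_edit_distance(h$d1_b, h$d2_b)$distance,
      banded_edit_distance(h$d1_a, h$d2_b)$distance +
        banded_edit_distance(h$d1_b, h$d2_a)$distance)
    expect_gt(lev, d)
  }
  expect_gte(recovered, 5L)
})
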