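test_that("biosphere boundary is inclusive for rare, exclusive for common", {
  m <- counts_at_depth(
    matrix(c(1, 2, 0), 3, 1, dimnames = list(c("A", "B", "C"), "S1")), 1000)
  part <- partition_biospheres(feature_table(m, is_rarefied = TRUE),
                               cutoff = 0.001)
  expect_equal(part$rare$counts["A", "S1"], 1)   # exactly at cutoff -> rare
  expect_equal(part$common$counts["B", "S1"], 2) # strictly above -> common
  expect_equal(part$rare$counts["C", "S1"] + part$common$counts["C", "S1"], 0)
  expect_error(partition_biospheres(m, cutoff = 1), "between 0 and 1")
  expect_error(partition_biospheres(m, cutoff = 0), "between 0 and 1")
})

test_that("partition reconstructs the input table exactly", {
  set.seed(10)
  m <- matrix(rpois(200, 3), 20, 10,
              dimnames = list(sprintf("A%02d", 1:20), sprintf("S%02d", 1:10)))
  for (co in c(0.002, 0.02, 0.2)) {
    part <- partition_biospheres(m, cutoff = co)
    expect_identical(part$rare$counts + part$common$counts,
                     feature_table(m)$counts)
    # an occurrence is in exactly one component
    expect_true(all(!(part$rare$counts > 0 & part$common$counts > 0)))
  }
})

test_that("h-index cutoff follows the rank-abundance crossing rule", {
  counts <- c(500, 100, 50, 10, 5, 3, 2, 1, 1, 1)
  expect_equal(sample_specific_cutoff(counts), 5 / 673)
  # recalibration multiplies by completeness S_obs / S_chao1
  expect_equal(sample_specific_cutoff(counts, recalibrate = TRUE),
               (5 / 673) * (10 / chao1(counts)))
  expect_equal(chao1(counts), 10 + 9 / 2) # F1 = 3, F2 = 1
  expect_equal(sample_specific_cutoff(c(1, 1, 1)), 1 / 3)
  expect_error(sample_specific_cutoff(c(0, 0)), "no positive")
  # divide direction inflates instead of shrinking
  expect_gt(sample_specific_cutoff(counts, recalibrate = TRUE,
                                   direction = "divide"),
            sample_specific_cutoff(counts))
})

test_that("rarity types follow the four occurrence rules", {
  # relative abundances across 3 samples at depth 10000, cutoff 0.1% (10 reads)
  rel <- matrix(c(
    5, 20, 1,    # rare, common, rare        -> conditionally_rare_common
    5, 2, 0,     # rare, rare, absent        -> permanently_rare
    1, 0, 0,     # rare once                 -> transiently_rare
    50, 30, 20   # common everywhere         -> permanently_common
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("A", 1:4), paste0("S", 1:3)))
  m <- counts_at_depth(rel, 10000)
  part <- partition_biospheres(feature_table(m, is_rarefied = TRUE),
                               cutoff = 0.001)
  ty <- classify_rarity_types(part)
  got <- setNames(as.character(ty$type), ty$asv)
  expect_identical(got[["A1"]], "conditionally_rare_common")
  expect_identical(got[["A2"]], "permanently_rare")
  expect_identical(got[["A3"]], "transiently_rare")
  expect_identical(got[["A4"]], "permanently_common")
  expect_false(any(ty$flagged[ty$asv %in% paste0("A", 1:4)]))
})

test_that("taxa common somewhere but never rare are flagged conditional", {
  rel <- matrix(c(30, 0, 0,
                  40, 40, 40), nrow = 2, byrow = TRUE,
                dimnames = list(c("X", "Y"), paste0("S", 1:3)))
  m <- counts_at_depth(rel, 10000)
  part <- partition_biospheres(feature_table(m, is_rarefied = TRUE),
                               cutoff = 0.001)
  ty <- classify_rarity_types(part)
  row_x <- ty[ty$asv == "X", ]
  expect_identical(as.character(row_x$type), "conditionally_rare_common")
  expect_true(row_x$flagged)
})

test_that("never-detected taxa are excluded from typing with a warning", {
  m <- matrix(c(6, 4, 0, 4, 6, 0), 3, 2,
              dimnames = list(c("A", "B", "Z"), c("S1", "S2")))
  part <- partition_biospheres(feature_table(m, is_rarefied = TRUE),
                               cutoff = 0.2)
  expect_warning(ty <- classify_rarity_types(part), "never-detected")
  expect_identical(ty$asv, c("A", "B"))
})

test_that("type counts partition the detected ASV set", {
  set.seed(21)
  m <- matrix(rpois(600, 2), 60, 10,
              dimnames = list(sprintf("A%02d", 1:60), sprintf("S%02d", 1:10)))
  m <- m[rowSums(m) > 0, ]
  part <- partition_biospheres(m, cutoff = 0.05)
  ty <- classify_rarity_types(part)
  expect_identical(nrow(ty), nrow(m))
  expect_identical(sum(table(ty$type)), nrow(m))
})

test_that("stricter cutoffs shrink the rare biosphere monotonically", {
  set.seed(3)
  ds <- simulate_dataset(scenario_config("neutral_drift", n_taxa = 150,
                                         design = c(2, 2, 2), depth = 2000,
                                         seed = 5))
  rare_share <- vapply(c(0.002, 0.001, 0.0005), function(co) {
    part <- partition_biospheres(ds$table, cutoff = co)
    sum(part$rare$counts) / sum(ds$table$counts)
  }, numeric(1))
  expect_true(all(diff(rare_share) <= 0))
})

test_that("raising the cutoff only moves taxa down the rarity lattice", {
  set.seed(31)
  ds <- simulate_dataset(scenario_config("neutral_drift", n_taxa = 120,
                                         design = c(2, 2, 2), depth = 1500,
                                         seed = 8))
  # a higher cutoff widens the rare biosphere: taxa can only move away
  # from permanently_common, never toward it
  rank_of <- c(permanently_common = 3, conditionally_rare_common = 2,
               permanently_rare = 1, transiently_rare = 1)
  lo <- suppressWarnings(
    classify_rarity_types(partition_biospheres(ds$table, 0.0005)))
  hi <- suppressWarnings(
    classify_rarity_types(partition_biospheres(ds$table, 0.002)))
  shared <- intersect(lo$asv, hi$asv)
  r_lo <- rank_of[as.character(lo$type[match(shared, lo$asv)])]
  r_hi <- rank_of[as.character(hi$type[match(shared, hi$asv)])]
  expect_true(all(r_hi <= r_lo))
})

test_that("sample-specific cutoffs flow through the partition", {
  set.seed(17)
  m <- matrix(rpois(300, 4) + rbinom(300, 1, 0.1) * 50, 30, 10,
              dimnames = list(sprintf("A%02d", 1:30), sprintf("S%02d", 1:10)))
  part <- partition_biospheres(m, cutoff = "sample_specific",
                               recalibrate = TRUE)
  expect_identical(part$cutoffs$mode[1], "sample_specific")
  expect_true(all(part$cutoffs$adjusted <= part$cutoffs$raw))
  expect_identical(part$rare$counts + part$common$counts,
                   feature_table(m)$counts)
})
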