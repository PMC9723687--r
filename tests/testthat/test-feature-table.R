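test_that("feature_table validates its invariants", {
  m <- matrix(1:6, 3, 2, dimnames = list(paste0("A", 1:3), c("S1", "S2")))
  ft <- feature_table(m)
  expect_s3_class(ft, "feature_table")
  expect_error(feature_table(unname(m)), "row names")
  m2 <- m; rownames(m2) <- c("A1", "A1", "A3")
  expect_error(feature_table(m2), "duplicate ASV")
  m3 <- m; m3[1, 1] <- -1
  expect_error(feature_table(m3), "non-negative")
  m4 <- m; m4[1, 1] <- 1.5
  expect_error(feature_table(m4), "non-negative integers")
  expect_error(feature_table(m, is_rarefied = TRUE), "column sums")
})

test_that("dataset loading cross-validates ids and applies tip policy", {
  dir <- withr::local_tempdir()
  m <- matrix(c(5L, 3L, 2L, 4L, 0L, 6L), 3, 2,
              dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  write.table(data.frame(asv_id = rownames(m), m, check.names = FALSE),
              file.path(dir, "table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  md <- data.frame(sample_id = c("S1", "S2"), stage = 1:2, time = 1,
                   replicate = 1)
  write.table(md, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ape::write.tree(ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);"),
                  file.path(dir, "tree.nwk"))

  ds <- load_dataset(file.path(dir, "table.tsv"), file.path(dir, "meta.tsv"),
                     file.path(dir, "tree.nwk"))
  expect_identical(dim(ds$table$counts), c(3L, 2L))
  expect_identical(ds$metadata$sample_id, c("S1", "S2"))
  expect_length(ds$dropped_asvs, 0)

  # sample missing from metadata is a hard error naming the sample
  md_bad <- md[1, , drop = FALSE]
  write.table(md_bad, file.path(dir, "meta_bad.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(
    load_dataset(file.path(dir, "table.tsv"), file.path(dir, "meta_bad.tsv"),
                 file.path(dir, "tree.nwk")),
    "S2")

  # ASV missing from tree: dropped with a warning under the default policy
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  ape::write.tree(tr2, file.path(dir, "tree2.nwk"))
  expect_warning(
    ds2 <- load_dataset(file.path(dir, "table.tsv"),
                        file.path(dir, "meta.tsv"),
                        file.path(dir, "tree2.nwk")),
    "dropped")
  expect_identical(rownames(ds2$table$counts), c("A", "B"))
  expect_error(
    suppressWarnings(load_dataset(file.path(dir, "table.tsv"),
                                  file.path(dir, "meta.tsv"),
                                  file.path(dir, "tree2.nwk"),
                                  missing_tip_policy = "error")),
    "missing from the tree")
})

test_that("BIOM-style TSV comments and transposed tables are handled", {
  dir <- withr::local_tempdir()
  writeLines(c("# Constructed from biom file",
               "#OTU ID\tS1\tS2", "A\t5\t4", "B\t3\t0"),
             file.path(dir, "biom.tsv"))
  ft <- read_feature_table(file.path(dir, "biom.tsv"))
  expect_identical(rownames(ft$counts), c("A", "B"))
  expect_identical(unname(ft$counts["A", ]), c(5, 4))

  writeLines(c("sample_id\tA\tB", "S1\t5\t3", "S2\t4\t0"),
             file.path(dir, "transposed.tsv"))
  expect_message(ft2 <- read_feature_table(file.path(dir, "transposed.tsv")),
                 "transposing")
  expect_identical(ft2$counts, ft$counts)
})

test_that("rarefaction subsamples to exact depth and drops shallow samples", {
  m <- matrix(c(30L, 20L, 0L, 100L, 0L, 0L, 25L, 10L, 5L), 3, 3,
              dimnames = list(paste0("A", 1:3), paste0("S", 1:3)))
  expect_warning(ft <- rarefy_table(m, 50, seed = 1), "S3")
  expect_true(ft$is_rarefied)
  expect_identical(colnames(ft$counts), c("S1", "S2"))
  expect_true(all(colSums(ft$counts) == 50))
  # sample at exactly the target depth comes back unchanged
  expect_identical(unname(ft$counts["A1", "S1"]), 30)
  expect_identical(unname(ft$counts["A2", "S1"]), 20)
  # single-taxon column keeps all reads in that taxon
  m2 <- matrix(c(100L, 0L), 2, 1, dimnames = list(c("A", "B"), "S1"))
  ft2 <- rarefy_table(m2, 50, seed = 1)
  expect_identical(unname(ft2$counts[, 1]), 50)
  expect_identical(rownames(ft2$counts), "A")
  expect_error(rarefy_table(m2, 1000), "exceeds every sample")
})

test_that("rarefaction is seed-reproducible and depth-exact across seeds", {
  set.seed(99)
  m <- matrix(rpois(80, 40), 8, 10,
              dimnames = list(paste0("A", 1:8), paste0("S", 1:10)))
  a <- rarefy_table(m, 100, seed = 7)
  b <- rarefy_table(m, 100, seed = 7)
  expect_identical(a$counts, b$counts)
  for (s in c(1, 2, 3)) {
    r <- rarefy_table(m, 100, seed = s)
    expect_true(all(colSums(r$counts) == 100))
  }
  c2 <- rarefy_table(m, 100, seed = 8)
  expect_false(identical(a$counts, c2$counts))
  # multiple draws come back as a list of independent tables
  lst <- rarefy_table(m, 100, seed = 1, n_draws = 3)
  expect_length(lst, 3)
  expect_true(all(vapply(lst, function(x) all(colSums(x$counts) == 100),
                         logical(1))))
})

test_that("chao1 matches closed-form fixtures and dominates observed richness", {
  expect_equal(chao1(c(50, 20, 10, 5, 2, 2, 1, 1, 1, 1)), 14)
  expect_equal(chao1(c(5, 10, 3, 7, 4)), 5) # no singletons or doubletons
  expect_equal(chao1(c(1, 1)), 3) # bias-corrected branch, F2 = 0
  expect_equal(chao1(integer(0)), 0)
  expect_equal(chao1(c(0, 0, 0)), 0)
  expect_error(chao1(c(-1, 2)), "non-negative")
  set.seed(4)
  for (i in 1:50) {
    v <- rpois(30, sample(1:5, 1))
    expect_gte(chao1(v), sum(v > 0))
  }
})

test_that("cophenetic distances are path sums with the tree's invariants", {
  D <- cophenetic_matrix(toy_tree())
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 6)
  expect_true(all(diag(D) == 0))
  expect_identical(D, t(D))
  # ultrametric tree: equal root-to-tip distances
  set.seed(2)
  tr <- ape::rcoal(10)
  expect_equal(var(ape::node.depth.edgelength(tr)[1:10]), 0, tolerance = 1e-12)
  tr_bad <- toy_tree(); tr_bad$tip.label[2] <- ""
  expect_error(cophenetic_matrix(tr_bad), "unlabeled")
  tr_nb <- toy_tree(); tr_nb$edge.length <- NULL
  expect_error(cophenetic_matrix(tr_nb), "branch lengths")
})
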