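test_that("rare-taxon filter uses a strict whole-dataset threshold", {
  m <- matrix(c(29999, 1,
                0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("big", "rare")))
  m["s2", ] <- c(0L, 0L)
  m <- m + 0L
  ct <- count_table(m)
  # 1 read of 30,000 (0.0033%) falls below the 0.005% default
  out <- filter_rare_taxa(ct)
  expect_equal(taxon_ids(out), "big")
  expect_equal(sample_ids(out), c("s1", "s2"))  # samples untouched

  # exactly at the threshold: retained ("less than" is strict)
  m2 <- matrix(c(59997L, 3L), 1, dimnames = list("s1", c("big", "edge")))
  expect_equal(taxon_ids(filter_rare_taxa(count_table(m2))),
               c("big", "edge"))

  expect_identical(filter_rare_taxa(ct, 0)$counts, ct$counts)
  expect_error(filter_rare_taxa(ct, 1.5), "\\[0, 1\\]")
})

test_that("rarefaction subsamples without replacement to equal depth", {
  ct <- random_count_table(6, 10, seed = 9, depth = 800)
  ct$counts[1, ] <- 0L; ct$counts[1, 1] <- 50L  # an under-depth sample
  r <- rarefy(ct, depth = 200, seed = 3)
  expect_true(all(rowSums(r$counts) == 200))
  expect_equal(attr(r, "excluded"), "s01")
  common <- intersect(rownames(r$counts), rownames(ct$counts))
  expect_true(all(r$counts[common, ] <= ct$counts[common, ]))
  # deterministic per seed
  expect_identical(rarefy(ct, 200, seed = 3)$counts, r$counts)
  expect_false(identical(rarefy(ct, 200, seed = 4)$counts, r$counts))
  # a sample at exactly the target depth passes through unchanged
  exact <- count_table(matrix(c(120L, 80L), 1,
                              dimnames = list("s1", c("a", "b"))))
  expect_identical(rarefy(exact, 200, seed = 1)$counts, exact$counts)
  expect_error(rarefy(ct, 10^6), "exceeds every sample")
})

test_that("rare-taxon filtering and rarefaction do not commute", {
  # a taxon just below the pre-rarefaction cut can survive the
  # post-rarefaction one and vice versa; the pipeline fixes filter -> rarefy
  withr::with_seed(5, {
    m <- cbind(matrix(rpois(40, 500), 4, 10), edge = c(2L, 0L, 0L, 0L))
    dimnames(m) <- list(sprintf("s%d", 1:4),
                        c(sprintf("t%02d", 1:10), "edge"))
    ct <- count_table(m)
    a <- rarefy(filter_rare_taxa(ct, 2e-4), depth = 300, seed = 1)
    b <- filter_rare_taxa(rarefy(ct, depth = 300, seed = 1), 2e-4)
    expect_false(identical(dim(a$counts), dim(b$counts)) &&
                   identical(a$counts, b$counts))
  })
})

test_that("taxon aggregation conserves the grand total", {
  ct <- random_count_table(4, 6, seed = 2)
  ident <- aggregate_taxa(ct, setNames(taxon_ids(ct), taxon_ids(ct)))
  expect_identical(unname(ident$counts), unname(ct$counts))

  map <- setNames(c("G1", "G1", "G2", "G2", "G2", NA), taxon_ids(ct))
  map <- map[!is.na(map)]
  agg <- aggregate_taxa(ct, map)
  expect_equal(sum(agg$counts), sum(ct$counts))
  expect_setequal(taxon_ids(agg), c("G1", "G2", "unclassified"))
  expect_equal(unname(agg$counts[, "G1"]),
               unname(rowSums(ct$counts[, 1:2])))

  m <- matrix(c(3L, 4L), 1, dimnames = list("s1", c("o1", "o2")))
  both <- aggregate_taxa(count_table(m), c(o1 = "g", o2 = "g"))
  expect_equal(unname(both$counts[1, "g"]), 7)
})

test_that("relative abundances are scale-invariant row simplices", {
  ct <- random_count_table(5, 8, seed = 3)
  rel <- to_relative(ct)
  expect_true(all(abs(rowSums(rel) - 1) < 1e-9))
  expect_equal(unname(to_relative(count_table(
    matrix(c(2L, 2L), 1, dimnames = list("s", c("a", "b")))))[1, ]),
    c(0.5, 0.5))
  scaled <- count_table(ct$counts * 3L)
  expect_equal(unclass(to_relative(scaled)), unclass(rel))
  zero <- ct; zero$counts[2, ] <- 0L
  expect_error(to_relative(count_table(zero$counts)), "s02")
})

test_that("low-biomass flagging partitions the cohort", {
  ct <- random_count_table(6, 5, seed = 4, depth = 100)
  ct$counts[3, ] <- 0L
  ct <- count_table(ct$counts)
  none <- flag_low_biomass(ct, 0)
  expect_length(none$flagged, 0)
  p <- flag_low_biomass(ct, 50)
  expect_true("s03" %in% p$flagged)
  expect_equal(nrow(p$analyzable$counts) + length(p$flagged), 6)
})

test_that("prevalence filter keeps abundant-and-prevalent taxa", {
  ct <- random_count_table(10, 6, seed = 6)
  ct$counts[, 6] <- 0L
  ct <- count_table(ct$counts)
  expect_identical(prevalence_filter_da(ct, 0, 0)$counts, ct$counts)
  filt <- prevalence_filter_da(ct, 0.001, 0.01)
  expect_false("t06" %in% taxon_ids(filt))
  # a taxon at 20% everywhere passes easy cuts
  expect_true("t01" %in% taxon_ids(
    prevalence_filter_da(ct, 0.001, 0.01)) ||
      any(to_relative(ct)[, "t01"] < 0.001))
  expect_error(prevalence_filter_da(ct, -1, 0), "\\[0, 1\\]")
})
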