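test_that("cohort simulation is a pure function of its seed", {
  cfg <- cohort_config(n_samples = 30, n_taxa = 12, K = 3,
                       driver_boost = 50, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$labels, b$labels)
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(simulate_cohort(cfg2)$table$counts,
                         a$table$counts))
})

test_that("boosted drivers dominate their components", {
  cfg <- cohort_config(n_samples = 120, n_taxa = 10, K = 3,
                       dirichlet_base = 0.2, driver_boost = 50,
                       depth_log_mean = log(1e4), seed = 3)
  sim <- simulate_cohort(cfg)
  rel <- to_relative(sim$table)
  for (k in 1:3) {
    mu <- colMeans(rel[sim$labels == k, , drop = FALSE])
    expect_equal(unname(which.max(mu)), k)  # driver taxa are taxa 1..K
  }
})

test_that("config validation catches malformed mixtures", {
  expect_error(cohort_config(10, 3, K = 5), "exceeds")
  expect_error(cohort_config(10, 5, K = 2, mixing_weights = c(0.6, 0.6)),
               "simplex")
  expect_error(cohort_config(10, 5, K = 2, driver_boost = 0.5), ">= 1")
  expect_error(cohort_config(10, 5, K = 2, driver_taxa = c(1, 1)),
               "distinct driver")
})

test_that("paired simulation couples or decouples timepoint classes", {
  c1 <- cohort_config(n_samples = 80, n_taxa = 10, K = 2, seed = 1)
  c2 <- cohort_config(n_samples = 80, n_taxa = 10, K = 2, seed = 2)
  coupled <- simulate_paired(c1, c2, association = 1, seed = 5)
  tab <- table(coupled$t1$labels, coupled$t2$labels)
  expect_equal(sum(diag(tab)), 80)  # identity mapping => diagonal

  # association = 0: cross-tab association tests keep their nominal level
  rej <- vapply(1:100, function(i) {
    p <- simulate_paired(c1, c2, association = 0, seed = 100 + i)
    ct <- table(p$t1$labels, p$t2$labels)
    suppressWarnings(chisq.test(ct)$p.value) < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12)

  # Cramer's V grows with the association parameter
  v_of <- function(assoc, seed) {
    p <- simulate_paired(c1, c2, association = assoc, seed = seed)
    ct <- table(p$t1$labels, p$t2$labels)
    chi <- suppressWarnings(chisq.test(ct, correct = FALSE)$statistic)
    sqrt(chi / sum(ct))
  }
  vs <- vapply(c(0, 0.5, 0.9), function(a) {
    mean(vapply(1:10, function(s) v_of(a, 7000 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
})

test_that("simulated trees cover the taxon set deterministically", {
  taxa <- sprintf("g%02d", 1:8)
  t1 <- simulate_tree(taxa, seed = 4)
  t2 <- simulate_tree(taxa, seed = 4)
  expect_setequal(t1$tip.label, taxa)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
  expect_error(simulate_tree("g1", seed = 1), "at least 2")

  cherry <- simulate_tree(c("a", "b"), seed = 1)
  expect_equal(ape::Ntip(cherry), 2)
})

test_that("metadata effects are recoverable and nulls are null", {
  labels <- setNames(rep(1:2, each = 250), sprintf("s%03d", 1:500))
  md <- simulate_metadata(labels, effects = list(
    bw = list(type = "continuous", means = c(1130, 1280), sd = 330),
    noise = list(type = "categorical", levels = c("x", "y"),
                 probs = c(0.5, 0.5))), seed = 11)
  expect_identical(md, simulate_metadata(labels, effects = list(
    bw = list(type = "continuous", means = c(1130, 1280), sd = 330),
    noise = list(type = "categorical", levels = c("x", "y"),
                 probs = c(0.5, 0.5))), seed = 11))
  # power: a 150 g shift at sd 330, n = 250/250, is detected
  expect_lt(t.test(md$bw ~ labels)$p.value, 0.01)
  # null categorical stays null across replicates
  rej <- vapply(1:60, function(i) {
    m <- simulate_metadata(labels, effects = list(
      g = list(type = "categorical", levels = c("x", "y"),
               probs = c(0.5, 0.5))), seed = 200 + i)
    suppressWarnings(chisq.test(table(m$g, labels))$p.value) < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.15)
  expect_error(simulate_metadata(labels, effects = list(
    g = list(type = "categorical", levels = c("x", "y"),
             probs = c(0.7, 0.7))), seed = 1), "sum to 1")
})
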