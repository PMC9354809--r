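test_that("permanova pseudo-F agrees with vegan and detects structure", {
  d <- two_cluster_dist(n_per = 10, sep = 50, seed = 4)
  groups <- rep(c("a", "b"), each = 10)
  res <- permanova(d, groups, n_perm = 999, seed = 1)
  # no random relabeling reproduces two tight, far clusters
  expect_equal(res$p_value, 0.001)
  ad <- vegan::adonis2(d ~ g, data = data.frame(g = groups),
                       permutations = 2)
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-9)
  expect_error(permanova(d, c("a", rep("b", 19)), n_perm = 9),
               "fewer than 2")
})

test_that("exhaustive permanova equals a brute-force oracle", {
  pts <- withr::with_seed(41, matrix(rnorm(12), 6, 2))
  rownames(pts) <- paste0("s", 1:6)
  d <- dist(pts)
  groups <- rep(c("a", "b"), each = 3)
  res <- permanova(d, groups, n_perm = "exact")
  # oracle: enumerate the 20 distinct assignments of 3 samples to group a,
  # scoring each with vegan's F (independent implementation)
  f_of <- function(assign_a) {
    g <- ifelse(seq_len(6) %in% assign_a, "a", "b")
    vegan::adonis2(d ~ g, data = data.frame(g = g), permutations = 2)$F[1]
  }
  f_all <- apply(combn(6, 3), 2, f_of)
  f_obs <- f_of(1:3)
  expect_equal(res$statistic, f_obs, tolerance = 1e-9)
  expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12))
})

test_that("mantel matches vegan and a full enumeration oracle", {
  withr::with_seed(43, {
    m1 <- matrix(rnorm(10), 5, 2); m2 <- matrix(rnorm(10), 5, 2)
  })
  rownames(m1) <- rownames(m2) <- paste0("s", 1:5)
  da <- dist(m1); db <- dist(m2)
  res <- mantel_test(da, db, n_perm = "exact")
  vg <- vegan::mantel(da, db, method = "spearman", permutations = 9)
  expect_equal(res$statistic, vg$statistic, tolerance = 1e-9)
  # oracle: all 5! simultaneous row/column permutations, inline
  ma <- as.matrix(da); mb <- as.matrix(db)
  lower <- lower.tri(ma)
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ]
  r_obs <- cor(ma[lower], mb[lower], method = "spearman")
  r_all <- apply(perms, 1, function(p) {
    p <- as.integer(p)
    cor(ma[lower], mb[p, p][lower], method = "spearman")
  })
  expect_equal(nrow(perms), 120)
  expect_equal(res$p_value, mean(r_all >= r_obs - 1e-12))

  expect_equal(mantel_test(da, da, n_perm = 99, seed = 1)$statistic, 1)
  db2 <- db; attr(db2, "Labels") <- paste0("x", 1:5)
  expect_error(mantel_test(da, db2), "same samples")
})

test_that("rank tests match exact small-sample enumeration", {
  res <- rank_tests(c(1, 2, 3, 4, 5, 6), rep(c("x", "y"), each = 3),
                    "wilcoxon_two_sample")
  expect_equal(res$p_value, 0.1)  # 2 of the 20 arrangements are as extreme
  same <- rank_tests(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3),
                     "wilcoxon_two_sample")
  expect_equal(same$p_value, 1)
  # kruskal with 2 groups equals wilcoxon's uncorrected normal approx
  withr::with_seed(47, {
    v <- rnorm(16); g <- rep(c("a", "b"), each = 8)
  })
  kw <- rank_tests(v, g, "kruskal")
  wx <- suppressWarnings(wilcox.test(v[g == "a"], v[g == "b"],
                                     exact = FALSE, correct = FALSE))
  expect_equal(kw$p_value, wx$p.value, tolerance = 1e-9)
  expect_error(rank_tests(1:3, rep("a", 3), "kruskal"), "2 non-empty")
})

test_that("spearman matches an exhaustive rank-permutation oracle", {
  expect_equal(spearman_corr(1:5, 2 * (1:5) + 1)$statistic, 1)
  expect_equal(spearman_corr(1:5, -(1:5))$statistic, -1)
  withr::with_seed(53, { x <- rnorm(5); y <- rnorm(5) })
  res <- spearman_corr(x, y)
  rho_obs <- cor(x, y, method = "spearman")
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ]
  rho_all <- apply(perms, 1, function(p) {
    cor(x, y[as.integer(p)], method = "spearman")
  })
  expect_equal(res$statistic, rho_obs)
  expect_equal(res$p_value, mean(abs(rho_all) >= abs(rho_obs) - 1e-12))
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("contingency tests follow the compatibility profile", {
  # 4x2 cross-tab: plain Pearson, df = 3
  edu <- matrix(c(24, 19, 30, 55, 11, 8, 7, 4), ncol = 2)
  r <- contingency_test(edu, "chisq")
  expect_equal(r$df, 3)
  expect_equal(round(r$p_value, 3), 0.011)
  # 2x2: Yates correction floored at zero
  sed <- matrix(c(81, 47, 20, 11), 2, byrow = TRUE)
  r2 <- contingency_test(sed, "chisq")
  expect_equal(r2$statistic, 0)
  expect_equal(round(r2$p_value, 3), 1)
  # Fisher on the diagonal 2x2: hypergeometric two-sided p = 1/3
  r3 <- contingency_test(matrix(c(2, 0, 0, 2), 2), "fisher")
  expect_equal(r3$p_value, 1 / 3, tolerance = 1e-9)
  expect_error(contingency_test(matrix(c(0, 0, 1, 2), 2), "chisq"),
               "empty margin")
  expect_error(contingency_test(matrix(c(1.5, 1, 1, 1), 2), "chisq"),
               "integers")
})

test_that("summary t-test matches its closed form", {
  eq <- t_test_summary(5, 1, 10, 5, 1, 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  a <- t_test_summary(0, 1, 10, 1, 1, 10)
  b <- t_test_summary(1, 1, 10, 0, 1, 10)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, -2.2360, tolerance = 1e-4)
  expect_equal(a$df, 18)
  # cross-check against t.test on raw data with matching summaries
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  ours <- t_test_summary(mean(x), sd(x), 4, mean(y), sd(y), 4)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(t_test_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(59, {
    p <- runif(30)
    expect_true(all(bh_adjust(p) >= p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  })
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("clr_da flags a planted fold change and respects the null", {
  withr::with_seed(61, {
    base <- rgamma(20, 2)
    counts <- t(sapply(1:60, function(i) {
      a <- base
      if (i > 30) a[1] <- a[1] * 10  # planted 10-fold shift in taxon 1
      p <- rgamma(20, a); p <- p / sum(p)
      as.integer(rmultinom(1, 5e3, p))
    }))
    dimnames(counts) <- list(sprintf("s%02d", 1:60),
                             sprintf("t%02d", 1:20))
  })
  ct <- count_table(counts)
  groups <- rep(c("a", "b"), each = 30)
  res <- clr_da(ct, groups, mc_instances = 16, seed = 3)
  expect_lt(res$p_adjusted[1], 0.05)
  expect_gt(res$effect[1], 0)
  expect_identical(res, clr_da(ct, groups, mc_instances = 16, seed = 3))

  # arbitrary split of one homogeneous group: nothing should survive BH
  null_ct <- count_table(counts[1:30, ])
  null_res <- clr_da(null_ct, rep(c("a", "b"), each = 15),
                     mc_instances = 16, seed = 4)
  expect_equal(sum(null_res$p_adjusted < 0.05), 0)
})

test_that("concordance keeps taxa significant in both with equal sign", {
  a <- data.frame(taxon = c("x", "y", "z"), effect = c(1, 1, -1),
                  p_adjusted = c(0.01, 0.01, 0.5))
  b <- data.frame(taxon = c("z", "y", "x"), effect = c(-1, 1, 1),
                  p_adjusted = c(0.01, 0.02, 0.2))
  expect_equal(concordant_da(a, b), "y")
  b_flip <- b; b_flip$effect[2] <- -1
  expect_equal(concordant_da(a, b_flip), character(0))
  expect_setequal(concordant_da(a, b, alpha = 1), c("x", "y", "z"))
  expect_error(concordant_da(a, b[1:2, ]), "different taxon sets")
})
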