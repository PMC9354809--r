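test_that("pam clustering recovers separated groups and degenerate k", {
  d <- dist(c(p1 = 0, p2 = 1, p3 = 10, p4 = 11))
  res <- pam_cluster(d, 2)
  expect_equal(unname(res$labels), c(1, 1, 2, 2))
  # k = n: each sample its own medoid, zero objective
  all_k <- pam_cluster(d, 4)
  expect_setequal(all_k$medoids, c("p1", "p2", "p3", "p4"))
  # a duplicate of a medoid joins that medoid's cluster
  d5 <- dist(c(p1 = 0, p2 = 1, p3 = 10, p4 = 11, p5 = 10))
  res5 <- pam_cluster(d5, 2)
  expect_equal(res5$labels[["p5"]], res5$labels[["p3"]])
  expect_error(pam_cluster(d, 9), "out of range")
})

test_that("calinski-harabasz matches the hand-computed 1-D case", {
  d <- dist(c(0, 1, 10, 11))
  # SSB = 100, SSW = 1 -> (100/1)/(1/2) = 200
  expect_equal(ch_index(d, c(1, 1, 2, 2)), 200)
  # coincident points within clusters: SSW = 0 -> infinite separation
  d0 <- dist(c(0, 0, 5, 5))
  expect_equal(ch_index(d0, c(1, 1, 2, 2)), Inf)
  expect_error(ch_index(d, c(1, 1, 1, 1)), "2 clusters")
})

test_that("mean silhouette width matches hand evaluation", {
  d <- dist(c(0, 1, 10, 11))
  s <- silhouette_width(d, c(1, 1, 2, 2))
  expect_equal(s, (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-12)
  expect_equal(silhouette_width(dist(c(0, 0, 9, 9)), c(1, 1, 2, 2)), 1)
  # all-coincident data: undefined widths collapse to 0 by convention
  expect_equal(silhouette_width(dist(rep(0, 4)), c(1, 2, 1, 2)), 0)
})

test_that("prediction strength separates real from spurious structure", {
  d <- two_cluster_dist(n_per = 10, sep = 50, seed = 2)
  expect_equal(prediction_strength(d, 2, n_splits = 10, seed = 1), 1)
  expect_identical(prediction_strength(d, 2, n_splits = 10, seed = 9),
                   prediction_strength(d, 2, n_splits = 10, seed = 9))
  # exchangeable data: k = 2 does not generalize
  d0 <- withr::with_seed(3, dist(matrix(rnorm(24 * 2), 24)))
  expect_lt(prediction_strength(d0, 2, n_splits = 20, seed = 1), 0.9)
  expect_error(prediction_strength(d, 11, n_splits = 2, seed = 1),
               "infeasible")
})

test_that("driver genera maximize within-cluster mean abundance", {
  rel <- rbind(s1 = c(A = 0.7, B = 0.2, C = 0.1),
               s2 = c(A = 0.5, B = 0.3, C = 0.2),
               s3 = c(A = 0.1, B = 0.1, C = 0.8))
  dr <- driver_genera(rel, c(1, 1, 2))
  expect_equal(unname(dr), c("A", "C"), ignore_attr = TRUE)
  # exact tie: lexicographically first, flagged
  tie <- rbind(s1 = c(B = 0.5, A = 0.5), s2 = c(B = 0.5, A = 0.5))
  dt <- driver_genera(tie, c(1, 1))
  expect_equal(unname(dt), "A", ignore_attr = TRUE)
  expect_equal(attr(dt, "ties"), "1")
})

test_that("the fit recovers simulated community structure", {
  cfg <- cohort_config(n_samples = 90, n_taxa = 20, K = 3,
                       dirichlet_base = 0.1, driver_boost = 100,
                       depth_log_mean = log(5e3), seed = 31)
  sim <- simulate_cohort(cfg)
  fit <- fit_enterotypes(sim$table, k_max = 6, n_splits = 5, seed = 1)
  expect_equal(fit$chosen_k, 3)
  expect_gte(adjusted_rand_index(fit$labels, sim$labels), 0.9)
  expect_equal(fit$chosen_k, which.max(fit$ch_index) + 1)  # argmax rule
  expect_true(all(fit$medoids %in% names(fit$labels)))
  # medoids belong to the clusters they represent
  med_labels <- fit$labels[fit$medoids]
  expect_equal(sort(unname(med_labels)), seq_len(fit$chosen_k))

  # chosen k and the partition are invariant to sample order
  perm <- withr::with_seed(8, sample(nrow(sim$table$counts)))
  shuf <- count_table(sim$table$counts[perm, ],
                      taxonomy = sim$table$taxonomy)
  fit2 <- fit_enterotypes(shuf, k_max = 6, n_splits = 5, seed = 1)
  expect_equal(fit2$chosen_k, fit$chosen_k)
  expect_equal(adjusted_rand_index(fit2$labels[names(fit$labels)],
                                   fit$labels), 1)
})

test_that("low-biomass samples form an appended class", {
  cfg <- config_neonatal(seed = 7)
  sim <- simulate_cohort(cfg)
  fit <- fit_enterotypes(sim$table, k_max = 8, n_splits = 5, seed = 1,
                         low_biomass_threshold = 1000)
  expect_equal(length(fit$low_biomass_samples), sum(sim$failed))
  expect_equal(fit$low_biomass_class, fit$chosen_k + 1L)
  expect_true(all(fit$labels[fit$low_biomass_samples] ==
                    fit$low_biomass_class))
  expect_length(fit$labels, nrow(sim$table$counts))
  # flagged samples never appear in the clustering distance matrix
  expect_false(any(fit$low_biomass_samples %in%
                     attr(fit$dist, "Labels")))
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(13, {
    for (i in 1:5) {
      a <- sample(1:3, 40, replace = TRUE)
      b <- sample(1:4, 40, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
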