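# Hypothesis tests and multiplicity correction: one-factor PERMANOVA and
# Mantel with exhaustive-enumeration modes, rank tests, Spearman
# correlation, contingency tests under the compatibility profile
# (Yates-corrected chi-squared for 2x2 tables, plain Pearson otherwise),
# a t-test on summary statistics, and Benjamini-Hochberg adjustment.
# Permutation p-values use the add-one convention
# (1 + exceedances) / (1 + n_perm) throughout; exhaustive modes divide the
# count of assignments at least as extreme (identity included) by the total.

# Pseudo-F for a one-factor partition of a squared-distance matrix
# (Anderson decomposition: SST = sum d^2 / n, SSW summed per group).
permanova_f <- function(d2, labels) {
  n <- nrow(d2)
  groups <- unique(labels)
  a <- length(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in groups) {
    sub <- d2[labels == g, labels == g, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / nrow(sub)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance: partitions the total
#' sum of squared dissimilarities by a grouping factor and assesses the
#' pseudo-F statistic by free permutation of the group labels. With
#' `n_perm = "exact"` all distinct label permutations are enumerated and
#' the p-value is the exact proportion of permutations (identity included)
#' whose statistic reaches the observed one.
#'
#' @param dist a `dist` object.
#' @param factor grouping vector, at least 2 levels with >= 2 samples each.
#' @param n_perm number of random permutations (default 999) or `"exact"`.
#' @param seed integer seed for random permutations.
#' @return A [test_result] with the pseudo-F and permutation p-value.
#' @export
permanova <- function(dist, factor, n_perm = 999, seed = 1L) {
  d2 <- as.matrix(dist)^2
  labels <- as.vector(factor)
  n <- nrow(d2)
  if (length(labels) != n) stop_("factor length != number of samples")
  sizes <- table(labels)
  if (length(sizes) < 2) stop_("need at least 2 groups")
  if (any(sizes < 2)) {
    stop_("group '%s' has fewer than 2 samples",
          names(sizes)[which(sizes < 2)[1]])
  }
  f_obs <- permanova_f(d2, labels)
  if (identical(n_perm, "exact")) {
    perms <- all_perms(n)
    f_perm <- apply(perms, 1, function(p) permanova_f(d2, labels[p]))
    p <- mean(f_perm >= f_obs - 1e-12)
    return(test_result("permanova", f_obs, p, n_used = n,
                       df = length(sizes) - 1, n_perm = nrow(perms),
                       notes = "exhaustive enumeration"))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      permanova_f(d2, labels[sample.int(n)]) >= f_obs - 1e-12
    }, logical(1)))
  })
  test_result("permanova", f_obs, (1 + exceed) / (1 + n_perm),
              n_used = n, df = length(sizes) - 1, n_perm = n_perm)
}

#' PERMANOVA over several factors with FDR correction
#'
#' Runs a marginal one-factor [permanova()] per column and applies
#' Benjamini-Hochberg adjustment across factors.
#'
#' @param dist a `dist` object.
#' @param factors data frame of grouping columns (missing values dropped
#'   per factor, complete-case).
#' @param n_perm,seed as in [permanova()].
#' @return A data frame of per-factor results with `p_adjusted`.
#' @export
permanova_screen <- function(dist, factors, n_perm = 999, seed = 1L) {
  dmat <- as.matrix(dist)
  res <- lapply(seq_along(factors), function(j) {
    f <- factors[[j]]
    ok <- !is.na(f)
    r <- permanova(as.dist(dmat[ok, ok]), f[ok], n_perm = n_perm,
                   seed = derive_seed(seed, j))
    r$method <- "permanova"
    r
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  out <- cbind(factor = names(factors), out)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Mantel test between two dissimilarity matrices
#'
#' Correlates the corresponding off-diagonal entries (Spearman by default)
#' and assesses significance by simultaneous row/column permutation of the
#' second matrix; one-sided (greater), add-one convention. With
#' `n_perm = "exact"` all `n!` permutations are enumerated.
#'
#' @param dist_a,dist_b `dist` objects over the same samples, same order.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of permutations (default 999) or `"exact"`.
#' @param seed integer seed.
#' @return A [test_result] carrying the correlation as statistic.
#' @export
mantel_test <- function(dist_a, dist_b, method = c("spearman", "pearson"),
                        n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  la <- attr(dist_a, "Labels"); lb <- attr(dist_b, "Labels")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stop_("distance matrices are not over the same samples in the same order")
  }
  ma <- as.matrix(dist_a); mb <- as.matrix(dist_b)
  if (!all(dim(ma) == dim(mb))) stop_("distance matrices differ in size")
  n <- nrow(ma)
  lower <- lower.tri(ma)
  r_obs <- cor(ma[lower], mb[lower], method = method)
  stat_for <- function(perm) cor(ma[lower], mb[perm, perm][lower],
                                 method = method)
  if (identical(n_perm, "exact")) {
    perms <- all_perms(n)
    r_perm <- apply(perms, 1, stat_for)
    p <- mean(r_perm >= r_obs - 1e-12)
    return(test_result("mantel", r_obs, p, n_used = n,
                       n_perm = nrow(perms),
                       notes = paste(method, "exhaustive enumeration")))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) stat_for(sample.int(n)) >= r_obs - 1e-12,
               logical(1)))
  })
  test_result("mantel", r_obs, (1 + exceed) / (1 + n_perm), n_used = n,
              n_perm = n_perm, notes = method)
}

#' Rank tests for group comparisons
#'
#' Two-sample Wilcoxon rank-sum (exact for small tie-free samples,
#' otherwise tie-corrected normal approximation with continuity
#' correction) or Kruskal-Wallis for two or more groups.
#'
#' @param values numeric observations.
#' @param groups grouping vector aligned to `values`.
#' @param mode `"wilcoxon_two_sample"` or `"kruskal"`.
#' @return A [test_result].
#' @export
rank_tests <- function(values, groups,
                       mode = c("wilcoxon_two_sample", "kruskal")) {
  mode <- match.arg(mode)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(as.factor(groups[ok]))
  if (any(table(groups) == 0) || nlevels(groups) < 2) {
    stop_("need at least 2 non-empty groups")
  }
  if (mode == "wilcoxon_two_sample") {
    if (nlevels(groups) != 2) stop_("wilcoxon needs exactly 2 groups")
    ht <- suppressWarnings(
      wilcox.test(values[groups == levels(groups)[1]],
                  values[groups == levels(groups)[2]], correct = TRUE))
    test_result("wilcoxon_rank_sum", unname(ht$statistic), ht$p.value,
                n_used = length(values),
                notes = ht$method)
  } else {
    ht <- kruskal.test(values, groups)
    test_result("kruskal_wallis", unname(ht$statistic), ht$p.value,
                n_used = length(values), df = unname(ht$parameter))
  }
}

#' Spearman rank correlation test
#'
#' Mid-ranked ties; exact p-value for small tie-free samples, otherwise the
#' t/Edgeworth approximation of [stats::cor.test()].
#'
#' @param x,y paired numeric vectors, `n >= 3` after complete-case removal.
#' @return A [test_result] with rho as statistic.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0) stop_("constant vector: rho undefined")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
  test_result("spearman", unname(ht$estimate), ht$p.value,
              n_used = length(x))
}

#' Contingency-table test under the compatibility profile
#'
#' `"chisq"`: Pearson chi-squared with `(r-1)(c-1)` degrees of freedom;
#' 2x2 tables receive the Yates continuity correction (each term floored
#' at zero). `"fisher"`: exact test — two-sided hypergeometric summation
#' for 2x2; full enumeration for small r x c tables, falling back to
#' seeded Monte Carlo (`1e5` tables) when enumeration is infeasible.
#' Complete-case rows are expected: drop a missing-value category upstream.
#'
#' @param tab matrix of non-negative integer cells (at least 2x2, positive
#'   margins).
#' @param method `"chisq"` or `"fisher"`.
#' @param seed integer seed for the Monte Carlo fallback.
#' @return A [test_result].
#' @export
contingency_test <- function(tab, method = c("chisq", "fisher"),
                             seed = 1L) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop_("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_("cells must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_("empty margin")
  }
  if (method == "chisq") {
    correct <- nrow(tab) == 2 && ncol(tab) == 2
    ht <- suppressWarnings(chisq.test(tab, correct = correct))
    test_result("chisq", unname(ht$statistic), ht$p.value,
                n_used = sum(tab), df = unname(ht$parameter),
                notes = if (correct) "Yates continuity correction" else
                  "plain Pearson")
  } else {
    ht <- tryCatch(
      fisher.test(tab),
      error = function(e) with_seed(seed,
        fisher.test(tab, simulate.p.value = TRUE, B = 1e5)))
    test_result("fisher", NA_real_, ht$p.value, n_used = sum(tab),
                notes = ht$method)
  }
}

#' Two-sample t-test from summary statistics
#'
#' Student's t on group means, standard deviations and sizes — usable
#' directly on published summary rows. Pooled-variance by default; Welch
#' by flag.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (`n >= 2`, `sd > 0`).
#' @param pooled pooled-variance Student t (default) or Welch if `FALSE`.
#' @return A [test_result] (two-sided).
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = TRUE) {
  if (n1 < 2 || n2 < 2) stop_("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_("standard deviations must be positive")
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  test_result(if (pooled) "t_pooled" else "t_welch", t,
              2 * pt(-abs(t), df), n_used = n1 + n2, df = df)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR correction with monotonicity enforcement; the mapping is
#' order-preserving and element-wise `>=` the raw p-values.
#'
#' @param p_values vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop_("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
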