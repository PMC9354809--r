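# End-to-end workflows: a cross-sectional enterotype analysis of one
# timepoint and a longitudinal comparison of two timepoints over the same
# children.

#' Cross-sectional enterotype analysis
#'
#' Runs the full single-timepoint pipeline: rare-taxon filtering and
#' rarefaction, enterotype fitting ([fit_enterotypes()]), principal
#' coordinates ordination with driver-genus vectors, alpha-diversity
#' comparisons across and against a reference enterotype, within-cluster
#' beta-dispersion comparisons, a marginal PERMANOVA screen over metadata
#' factors with BH correction, and a univariate association screen of
#' metadata against enterotype membership.
#'
#' @param counts a [count_table].
#' @param tree optional rooted `phylo` (enables the UniFrac PERMANOVA).
#' @param metadata optional data frame, row names = sample ids; factor
#'   columns enter the PERMANOVA and association screens, numeric columns
#'   the association screen only.
#' @param min_taxon_fraction rare-taxon cut (default `5e-5`).
#' @param rarefy_depth `"min"`, an integer, or `NA` to skip rarefaction.
#' @param low_biomass_threshold reads below which a sample joins the
#'   appended low-biomass class.
#' @param k_max,pseudocount as in [fit_enterotypes()].
#' @param reference_class cluster id used as the reference for pairwise
#'   comparisons (default 1).
#' @param n_perm permutations for PERMANOVA/envfit (default 999).
#' @param seed integer seed; every stochastic stage derives its stream
#'   from it.
#' @return An object of class `cross_sectional_analysis`.
#' @export
run_cross_sectional <- function(counts, tree = NULL, metadata = NULL,
                                min_taxon_fraction = 5e-5,
                                rarefy_depth = "min",
                                low_biomass_threshold = 0,
                                k_max = 10, pseudocount = 1e-6,
                                reference_class = 1, n_perm = 999,
                                seed = 1L) {
  stopifnot(inherits(counts, "count_table"))
  filtered <- filter_rare_taxa(counts, min_taxon_fraction)
  part <- flag_low_biomass(filtered, low_biomass_threshold)
  work <- part$analyzable
  if (!identical(rarefy_depth, NA)) {
    work <- rarefy(work, depth = rarefy_depth, seed = derive_seed(seed, 1))
  }
  # flagged samples rejoin (unrarefied) so the fit carries the extra class
  if (length(part$flagged) > 0) {
    flagged_rows <- filtered$counts[part$flagged, colnames(work$counts),
                                    drop = FALSE]
    work <- count_table(rbind(work$counts, flagged_rows),
                        taxonomy = work$taxonomy)
  }
  fit <- fit_enterotypes(work, k_max = k_max, pseudocount = pseudocount,
                         seed = derive_seed(seed, 2),
                         low_biomass_threshold = low_biomass_threshold)
  ord <- pcoa(fit$dist, n_axes = 2)
  driver_vars <- fit$rel_abundance[rownames(ord$points),
                                   unique(fit$driver_genus), drop = FALSE]
  envfit_res <- envfit_vectors(ord, as.data.frame(driver_vars),
                               n_perm = n_perm, seed = derive_seed(seed, 3))
  analyzable_ids <- rownames(fit$rel_abundance)
  cl <- fit$labels[analyzable_ids]
  analyzable_tab <- count_table(work$counts[analyzable_ids, , drop = FALSE],
                                taxonomy = work$taxonomy)
  alpha <- list(chao1 = alpha_diversity(analyzable_tab, "chao1"),
                shannon = alpha_diversity(analyzable_tab, "shannon"))
  alpha_overall <- lapply(alpha, function(v) rank_tests(v, cl, "kruskal"))
  alpha_vs_ref <- lapply(alpha, function(v) {
    other <- setdiff(sort(unique(cl)), reference_class)
    res <- lapply(other, function(g) {
      keep <- cl %in% c(reference_class, g)
      rank_tests(v[keep], cl[keep], "wilcoxon_two_sample")
    })
    names(res) <- paste0("cluster", other)
    res
  })
  dmat <- as.matrix(fit$dist)
  within_d <- lapply(sort(unique(cl)), function(g) {
    sub <- dmat[cl == g, cl == g, drop = FALSE]
    sub[upper.tri(sub)]
  })
  names(within_d) <- paste0("cluster", sort(unique(cl)))
  ref_d <- within_d[[paste0("cluster", reference_class)]]
  beta_dispersion <- lapply(
    setdiff(names(within_d), paste0("cluster", reference_class)),
    function(nm) {
      vals <- c(ref_d, within_d[[nm]])
      grp <- rep(c("ref", nm), c(length(ref_d), length(within_d[[nm]])))
      rank_tests(vals, grp, "wilcoxon_two_sample")
    })
  names(beta_dispersion) <- setdiff(names(within_d),
                                    paste0("cluster", reference_class))
  permanova_res <- NULL
  assoc <- NULL
  if (!is.null(metadata)) {
    md <- metadata[analyzable_ids, , drop = FALSE]
    factors <- md[, vapply(md, is.factor, logical(1)), drop = FALSE]
    if (ncol(factors) > 0) {
      permanova_res <- permanova_screen(fit$dist, factors, n_perm = n_perm,
                                        seed = derive_seed(seed, 4))
    }
    assoc <- association_screen(metadata, fit$labels,
                                seed = derive_seed(seed, 5))
  }
  structure(list(fit = fit, ordination = ord, envfit = envfit_res,
                 alpha = alpha, alpha_overall = alpha_overall,
                 alpha_vs_reference = alpha_vs_ref,
                 beta_dispersion = beta_dispersion,
                 permanova = permanova_res, association = assoc,
                 params = list(min_taxon_fraction = min_taxon_fraction,
                               rarefy_depth = rarefy_depth,
                               low_biomass_threshold = low_biomass_threshold,
                               k_max = k_max, pseudocount = pseudocount,
                               reference_class = reference_class,
                               n_perm = n_perm, seed = seed)),
            class = "cross_sectional_analysis")
}

#' Univariate association screen of covariates against class labels
#'
#' Complete-case per variable. Categorical covariates are cross-tabulated
#' against the labels and tested with the compatibility-profile chi-squared
#' ([contingency_test()]); continuous covariates use Student's t when the
#' labels have two levels and Kruskal-Wallis otherwise.
#'
#' @param metadata data frame, row names = sample ids.
#' @param labels class label per sample (named).
#' @param seed integer seed (Monte Carlo fallback in sparse tables).
#' @return Data frame: `variable`, `method`, `statistic`, `p_value`,
#'   `n_used`.
#' @export
association_screen <- function(metadata, labels, seed = 1L) {
  ids <- intersect(rownames(metadata), names(labels))
  md <- metadata[ids, , drop = FALSE]
  labs <- factor(labels[ids])
  rows <- lapply(names(md), function(v) {
    x <- md[[v]]
    ok <- !is.na(x)
    r <- if (is.numeric(x)) {
      g <- droplevels(labs[ok])
      if (nlevels(g) == 2) {
        ht <- t.test(x[ok][g == levels(g)[1]], x[ok][g == levels(g)[2]],
                     var.equal = TRUE)
        test_result("t_pooled", unname(ht$statistic), ht$p.value,
                    n_used = sum(ok), df = unname(ht$parameter))
      } else {
        rank_tests(x[ok], g, "kruskal")
      }
    } else {
      tab <- table(droplevels(labs[ok]), droplevels(factor(x[ok])))
      contingency_test(as.matrix(tab), "chisq", seed = seed)
    }
    data.frame(variable = v, method = r$method, statistic = r$statistic,
               p_value = r$p_value, n_used = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Longitudinal comparison of two timepoints
#'
#' Fits enterotypes at each timepoint, then — over the samples present and
#' analyzable at both — correlates alpha diversity across timepoints
#' (Spearman), compares alpha diversity between timepoints (Wilcoxon
#' rank-sum), runs Mantel tests per beta-diversity metric, and tests the
#' enterotype cross-tabulation (including the low-biomass class as its own
#' category) with Fisher's exact test.
#'
#' @param counts_t1,counts_t2 [count_table]s with overlapping sample ids.
#' @param tree_t1,tree_t2 optional trees enabling UniFrac Mantel tests.
#' @param low_biomass_threshold_t1,low_biomass_threshold_t2 flagging
#'   thresholds per timepoint.
#' @param k_max,pseudocount,n_perm,seed as in [run_cross_sectional()].
#' @return An object of class `longitudinal_comparison`: per-timepoint
#'   fits, `alpha_correlation`, `alpha_change`, `mantel`, `crosstab`,
#'   `fisher`.
#' @export
run_longitudinal <- function(counts_t1, counts_t2,
                             tree_t1 = NULL, tree_t2 = NULL,
                             low_biomass_threshold_t1 = 0,
                             low_biomass_threshold_t2 = 0,
                             k_max = 10, pseudocount = 1e-6,
                             n_perm = 999, seed = 1L) {
  common <- intersect(rownames(counts_t1$counts), rownames(counts_t2$counts))
  if (length(common) == 0) stop_("no samples shared between timepoints")
  fit1 <- fit_enterotypes(counts_t1, k_max = k_max,
                          pseudocount = pseudocount,
                          seed = derive_seed(seed, 1),
                          low_biomass_threshold = low_biomass_threshold_t1)
  fit2 <- fit_enterotypes(counts_t2, k_max = k_max,
                          pseudocount = pseudocount,
                          seed = derive_seed(seed, 2),
                          low_biomass_threshold = low_biomass_threshold_t2)
  # cross-timepoint statistics on samples analyzable at both timepoints
  ok <- setdiff(common, union(fit1$low_biomass_samples,
                              fit2$low_biomass_samples))
  t1 <- count_table(counts_t1$counts[ok, , drop = FALSE],
                    taxonomy = counts_t1$taxonomy)
  t2 <- count_table(counts_t2$counts[ok, , drop = FALSE],
                    taxonomy = counts_t2$taxonomy)
  alpha_correlation <- list()
  alpha_change <- list()
  for (idx in c("chao1", "shannon")) {
    a1 <- alpha_diversity(t1, idx); a2 <- alpha_diversity(t2, idx)
    alpha_correlation[[idx]] <- spearman_corr(a1, a2)
    alpha_change[[idx]] <- rank_tests(c(a1, a2),
                                      rep(c("t1", "t2"), each = length(a1)),
                                      "wilcoxon_two_sample")
  }
  mantel <- list(
    braycurtis = mantel_test(beta_diversity(t1, "braycurtis"),
                             beta_diversity(t2, "braycurtis"),
                             n_perm = n_perm, seed = derive_seed(seed, 3)))
  if (!is.null(tree_t1) && !is.null(tree_t2)) {
    mantel$unifrac <- mantel_test(
      beta_diversity(t1, "unifrac", tree = tree_t1),
      beta_diversity(t2, "unifrac", tree = tree_t2),
      n_perm = n_perm, seed = derive_seed(seed, 4))
  }
  labs1 <- fit1$labels[common]; labs2 <- fit2$labels[common]
  crosstab <- table(t1 = labs1, t2 = labs2)
  fisher <- contingency_test(as.matrix(crosstab), "fisher",
                             seed = derive_seed(seed, 5))
  structure(list(fit_t1 = fit1, fit_t2 = fit2,
                 common_samples = common, analyzable_both = ok,
                 alpha_correlation = alpha_correlation,
                 alpha_change = alpha_change,
                 mantel = mantel, crosstab = crosstab, fisher = fisher,
                 params = list(k_max = k_max, pseudocount = pseudocount,
                               n_perm = n_perm, seed = seed)),
            class = "longitudinal_comparison")
}

#' @export
print.cross_sectional_analysis <- function(x, ...) {
  cat("Cross-sectional enterotype analysis\n")
  print(x$fit)
  cat(sprintf("alpha overall (Kruskal-Wallis): chao1 p = %.4g, shannon p = %.4g\n",
              x$alpha_overall$chao1$p_value,
              x$alpha_overall$shannon$p_value))
  if (!is.null(x$permanova)) {
    cat("PERMANOVA screen:\n")
    print(x$permanova[, c("factor", "statistic", "p_value", "p_adjusted")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
print.longitudinal_comparison <- function(x, ...) {
  cat("Longitudinal comparison\n")
  cat(sprintf("  t1: k = %d (+%d low-biomass); t2: k = %d\n",
              x$fit_t1$chosen_k, length(x$fit_t1$low_biomass_samples),
              x$fit_t2$chosen_k))
  for (idx in names(x$alpha_correlation)) {
    r <- x$alpha_correlation[[idx]]
    cat(sprintf("  alpha %s: rho = %.3f, p = %.3f\n", idx,
                r$statistic, r$p_value))
  }
  for (m in names(x$mantel)) {
    r <- x$mantel[[m]]
    cat(sprintf("  mantel %s: r = %.3f, p = %.3f\n", m,
                r$statistic, r$p_value))
  }
  cat(sprintf("  enterotype cross-tab Fisher p = %.3f\n", x$fisher$p_value))
  invisible(x)
}
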