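# Simplified compositional differential-abundance stage. This is an
# in-package CLR + Wilcoxon procedure (Monte-Carlo Dirichlet instances over
# the counts, centered log-ratio transform, per-taxon rank test, p-values
# averaged over instances, BH across taxa), together with the two-method
# concordance-intersection rule applied to any pair of differential
# abundance result lists.

#' Compositional differential-abundance test (CLR + Wilcoxon)
#'
#' For each of `mc_instances` Monte-Carlo instances, per-sample
#' compositions are drawn from `Dirichlet(counts + 0.5)`, transformed by
#' the centered log-ratio, and each taxon is compared between the two
#' groups with a Wilcoxon rank-sum test (normal approximation). Raw
#' p-values are averaged over instances and BH-adjusted across taxa.
#' The effect reported per taxon is the mean between-group difference of
#' median CLR values (group 2 minus group 1).
#'
#' @param table a [count_table], ideally pre-filtered with
#'   [prevalence_filter_da()].
#' @param groups two-level grouping vector aligned to samples (each level
#'   needs >= 2 samples).
#' @param mc_instances Monte-Carlo instances (default 128).
#' @param seed integer seed.
#' @return A data frame, one row per taxon: `taxon`, `effect`, `p_value`,
#'   `p_adjusted`.
#' @export
clr_da <- function(table, groups, mc_instances = 128, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop_("groups must have exactly 2 levels")
  if (any(table(groups) < 2)) stop_("each group needs >= 2 samples")
  counts <- table$counts
  n <- nrow(counts); p <- ncol(counts)
  g1 <- groups == levels(groups)[1]
  with_seed(seed, {
    pmat <- matrix(0, mc_instances, p)
    emat <- matrix(0, mc_instances, p)
    for (inst in seq_len(mc_instances)) {
      clr <- t(apply(counts + 0.5, 1, function(row) {
        comp <- rdirichlet1(row)
        lg <- log(comp)
        lg - mean(lg)
      }))
      for (j in seq_len(p)) {
        pmat[inst, j] <- suppressWarnings(
          wilcox.test(clr[g1, j], clr[!g1, j], exact = FALSE)$p.value)
        emat[inst, j] <- stats::median(clr[!g1, j]) -
          stats::median(clr[g1, j])
      }
    }
    p_raw <- colMeans(pmat)
    data.frame(taxon = colnames(counts),
               effect = colMeans(emat),
               p_value = p_raw,
               p_adjusted = bh_adjust(p_raw),
               row.names = NULL)
  })
}

#' Concordant differentially abundant taxa between two methods
#'
#' Differential-abundance callers disagree often enough that only taxa
#' flagged by two independent methods, with the same effect direction, are
#' retained.
#'
#' @param res_a,res_b data frames with columns `taxon`, `effect`,
#'   `p_adjusted` over the same taxon set (e.g. from [clr_da()]).
#' @param alpha adjusted-significance cutoff (default 0.05).
#' @return Character vector of concordant taxa.
#' @export
concordant_da <- function(res_a, res_b, alpha = 0.05) {
  if (!setequal(res_a$taxon, res_b$taxon)) {
    stop_("result lists cover different taxon sets")
  }
  b <- res_b[match(res_a$taxon, res_b$taxon), ]
  hit <- res_a$p_adjusted < alpha & b$p_adjusted < alpha &
    sign(res_a$effect) == sign(b$effect)
  res_a$taxon[hit]
}
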