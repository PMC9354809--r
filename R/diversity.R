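# Alpha diversity (Chao1, Shannon) and beta diversity (Bray-Curtis,
# unweighted UniFrac, square-root Jensen-Shannon divergence).

#' Per-sample alpha diversity
#'
#' Chao1 richness uses the bias-corrected estimator
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` by default (defined even when no
#' doubletons occur); the classic `S_obs + F1^2 / (2 F2)` form is available.
#' Shannon entropy is `-sum p_i log p_i` over non-zero proportions, natural
#' log by default.
#'
#' @param table a [count_table]; Chao1 requires integer counts (it uses
#'   singleton and doubleton tallies).
#' @param index `"chao1"` or `"shannon"`.
#' @param base logarithm base for Shannon (default `exp(1)`).
#' @param bias_corrected use the bias-corrected Chao1 (default `TRUE`).
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, index = c("chao1", "shannon"),
                            base = exp(1), bias_corrected = TRUE) {
  stopifnot(inherits(table, "count_table"))
  index <- match.arg(index)
  x <- table$counts
  if (any(rowSums(x) == 0)) stop_("all-zero sample present")
  if (index == "shannon") {
    vals <- vegan::diversity(x, index = "shannon", base = base)
  } else {
    vals <- apply(x, 1, function(row) {
      s_obs <- sum(row > 0)
      f1 <- sum(row == 1)
      f2 <- sum(row == 2)
      if (bias_corrected) {
        s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
      } else if (f2 > 0) {
        s_obs + f1^2 / (2 * f2)
      } else {
        s_obs + f1 * (f1 - 1) / 2  # classic form's F2 = 0 limit
      }
    })
  }
  setNames(as.numeric(vals), rownames(x))
}

# Jensen-Shannon divergence matrix on rows of a relative-abundance matrix.
# Zeros are replaced by `pseudocount` and rows renormalized first.
jsd_matrix <- function(rel, pseudocount) {
  p <- rel
  p[p == 0] <- pseudocount
  p <- p / rowSums(p)
  n <- nrow(p)
  # H(m) - (H(p) + H(q))/2 with H in nats
  h <- function(v) -sum(v * log(v))
  hs <- apply(p, 1, h)
  out <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- (p[i, ] + p[j, ]) / 2
      d <- h(m) - (hs[i] + hs[j]) / 2
      out[i, j] <- out[j, i] <- max(d, 0)
    }
  }
  out
}

#' Between-sample dissimilarity matrix
#'
#' * `braycurtis`: `sum |x_i - y_i| / sum (x_i + y_i)` on counts or
#'   fractions (via [vegan::vegdist()]).
#' * `unifrac`: unweighted (incidence-based) UniFrac, the fraction of tree
#'   branch length leading to taxa found in only one of the two samples
#'   (via [picante::unifrac()]); requires every taxon on the tree.
#' * `sqrt_jsd`: square root of the Jensen-Shannon divergence (natural log)
#'   between relative-abundance profiles, with zeros replaced by a
#'   pseudocount and rows renormalized. The square root is taken because
#'   JSD itself violates the triangle inequality while its root is a
#'   proper metric — the clustering distance for enterotyping.
#'
#' @param x a [count_table] or a relative-abundance matrix (rows = samples).
#' @param metric `"braycurtis"`, `"unifrac"` or `"sqrt_jsd"`.
#' @param tree rooted `phylo` covering all taxa (required for UniFrac).
#' @param pseudocount zero replacement for `sqrt_jsd` (default `1e-6`).
#' @return A `dist` object keyed by sample ids.
#' @export
beta_diversity <- function(x, metric = c("braycurtis", "unifrac", "sqrt_jsd"),
                           tree = NULL, pseudocount = 1e-6) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "count_table")) x$counts else unclass(x)
  if (!is.matrix(m)) stop_("x must be a count_table or a matrix")
  if (metric == "braycurtis") {
    return(vegan::vegdist(m, method = "bray"))
  }
  if (metric == "unifrac") {
    if (is.null(tree)) stop_("unifrac requires a tree")
    missing <- setdiff(colnames(m), tree$tip.label)
    if (length(missing) > 0) {
      stop_("taxa missing from tree: %s", paste(missing, collapse = ", "))
    }
    return(picante::unifrac(m, tree))
  }
  rel <- m / rowSums(m)
  as.dist(sqrt(jsd_matrix(rel, pseudocount)))
}
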