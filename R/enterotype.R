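# Enterotype classification: PAM on the sqrt-JSD matrix, cluster-number
# selection by the Calinski-Harabasz index, cross-validated by mean
# silhouette width and prediction strength, with a driver genus named per
# cluster.

#' Partition samples around medoids
#'
#' Deterministic k-medoids (BUILD initialization followed by SWAP) on a
#' precomputed dissimilarity matrix, via [cluster::pam()]. No randomness is
#' involved, so enterotype partitions are reproducible without a seed.
#'
#' @param dist a `dist` object.
#' @param k number of clusters, `2 <= k <= n`.
#' @return A list: `labels` (integer cluster per sample, named) and
#'   `medoids` (one sample id per cluster).
#' @export
pam_cluster <- function(dist, k) {
  n <- attr(dist, "Size")
  if (k < 1 || k > n) stop_("k = %d out of range for n = %d", k, n)
  if (k == n) {  # degenerate: every sample its own medoid, zero objective
    labs <- setNames(seq_len(n), attr(dist, "Labels"))
    return(list(labels = labs, medoids = attr(dist, "Labels")))
  }
  fit <- cluster::pam(dist, k, diss = TRUE, keep.diss = FALSE)
  labs <- setNames(as.integer(fit$clustering), attr(dist, "Labels"))
  list(labels = labs, medoids = as.character(fit$medoids))
}

# Embed a dissimilarity matrix by classical scaling, keeping axes with
# positive eigenvalues. Shared by the CH index and prediction strength.
pcoa_embed <- function(dist) {
  n <- attr(dist, "Size")
  sc <- suppressWarnings(cmdscale(dist, k = n - 1, eig = TRUE))
  eig <- sc$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  pts <- sc$points[, seq_len(min(length(pos), ncol(sc$points))), drop = FALSE]
  rownames(pts) <- attr(dist, "Labels")
  pts
}

#' Calinski-Harabasz index of a partition
#'
#' The classical CH criterion is defined on Euclidean coordinates, so the
#' dissimilarity matrix is first embedded by principal coordinates (axes
#' with positive eigenvalues); CH is then
#' `[SSB / (k - 1)] / [SSW / (n - k)]` from between/within sums of squared
#' distances to centroids in that embedding. A partition with zero
#' within-cluster scatter returns `Inf`.
#'
#' @param dist a `dist` object.
#' @param labels cluster assignment per sample (>= 2 non-empty clusters).
#' @return A single numeric value.
#' @export
ch_index <- function(dist, labels) {
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  n <- length(labels)
  if (k < 2) stop_("need at least 2 clusters")
  if (any(tabulate(labels, k) == 0)) stop_("empty cluster")
  pts <- pcoa_embed(dist)
  grand <- colMeans(pts)
  ssb <- 0; ssw <- 0
  for (g in seq_len(k)) {
    sub <- pts[labels == g, , drop = FALSE]
    cen <- colMeans(sub)
    ssw <- ssw + sum(sweep(sub, 2, cen)^2)
    ssb <- ssb + nrow(sub) * sum((cen - grand)^2)
  }
  if (ssw <= .Machine$double.eps * ssb) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Mean silhouette width of a partition
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean within-cluster
#' dissimilarity (self excluded) and `b` the smallest mean dissimilarity to
#' another cluster. Singleton clusters — and samples for which both `a` and
#' `b` vanish (coincident points) — contribute 0 by convention.
#'
#' @inheritParams ch_index
#' @return Mean silhouette width over all samples.
#' @export
silhouette_width <- function(dist, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop_("need at least 2 clusters")
  s <- cluster::silhouette(labels, dist)[, "sil_width"]
  s[!is.finite(s)] <- 0
  mean(s)
}

#' Prediction strength of a k-cluster solution
#'
#' Cross-validation of the cluster count: the samples are split 50/50,
#' each half is PAM-clustered at `k`, test-half samples are assigned to the
#' nearest training medoid, and the score for the split is the minimum over
#' test clusters of the proportion of within-cluster test pairs that the
#' training medoids also co-assign. The reported value is the mean over
#' `n_splits` random splits. Values near 1 indicate that the cluster
#' structure generalizes; rule-of-thumb support requires about 0.8-0.9.
#'
#' @param dist a `dist` object.
#' @param k number of clusters (each half must hold at least `k` samples).
#' @param n_splits number of random 50/50 splits (default 20).
#' @param seed integer seed; the result is deterministic per seed.
#' @return Mean prediction strength over splits.
#' @export
prediction_strength <- function(dist, k, n_splits = 20, seed = 1L) {
  dmat <- as.matrix(dist)
  n <- nrow(dmat)
  half <- n %/% 2
  if (k < 2 || k > half) stop_("k = %d infeasible for half size %d", k, half)
  with_seed(seed, {
    scores <- vapply(seq_len(n_splits), function(s) {
      idx <- sample.int(n)
      train <- sort(idx[seq_len(half)])
      test <- sort(idx[(half + 1):n])
      dtr <- as.dist(dmat[train, train])
      dte <- as.dist(dmat[test, test])
      ptr <- pam_cluster(dtr, k)
      pte <- pam_cluster(dte, k)
      med_idx <- match(ptr$medoids, rownames(dmat))
      # test samples assigned to the nearest training medoid
      assign_tr <- apply(dmat[test, med_idx, drop = FALSE], 1, which.min)
      min(vapply(seq_len(k), function(g) {
        members <- which(pte$labels == g)
        m <- length(members)
        if (m < 2) return(1)
        co <- outer(assign_tr[members], assign_tr[members], "==")
        sum(co[lower.tri(co)]) / (m * (m - 1) / 2)
      }, numeric(1)))
    }, numeric(1))
    mean(scores)
  })
}

#' Driver genus of each cluster
#'
#' The genus with the highest mean relative abundance within a cluster is
#' its main contributor and gives the enterotype its name. Exact ties are
#' broken lexicographically and flagged.
#'
#' @param relabund relative-abundance matrix (rows = samples).
#' @param labels cluster assignment per sample, aligned to rows.
#' @return Named character vector, one genus per cluster; ties are recorded
#'   in `attr(, "ties")`.
#' @export
driver_genera <- function(relabund, labels) {
  m <- unclass(relabund)
  labels <- as.factor(labels)
  ties <- character(0)
  out <- vapply(levels(labels), function(g) {
    mu <- colMeans(m[labels == g, , drop = FALSE])
    top <- sort(names(mu)[mu == max(mu)])
    if (length(top) > 1) ties <<- c(ties, g)
    top[1]
  }, character(1))
  attr(out, "ties") <- ties
  out
}

#' Fit enterotypes to a count table
#'
#' The full classification procedure: low-biomass samples are flagged and
#' set aside; relative genus abundances of the analyzable samples yield a
#' square-root Jensen-Shannon dissimilarity matrix; PAM partitions are
#' fitted for every `k` in `2..k_max`; the Calinski-Harabasz index selects
#' the cluster count (ties going to the smaller `k`), with mean silhouette
#' width and prediction strength reported as cross-validation — they do not
#' override the CH choice; each cluster is named after its driver genus.
#' Flagged samples are appended as one extra low-biomass class (cluster id
#' `chosen_k + 1`), excluded from the distance computation but retained so
#' that cross-tabulations cover the full cohort.
#'
#' @param table a [count_table] (genus level).
#' @param k_max largest cluster count tried (default 10; capped below the
#'   analyzable sample count and prediction-strength half size).
#' @param pseudocount zero replacement for the JSD (default `1e-6`).
#' @param seed integer seed (used only by prediction strength).
#' @param low_biomass_threshold read total below which a sample is flagged
#'   (default 0 = no flagging).
#' @param n_splits prediction-strength splits (default 20).
#' @return An object of class `enterotype_fit` with fields `k_grid`,
#'   `ch_index`, `mean_silhouette`, `prediction_strength`, `chosen_k`,
#'   `labels` (integer per sample over the full cohort), `medoids`,
#'   `driver_genus`, `low_biomass_class`, `low_biomass_samples`, `dist`,
#'   and `rel_abundance`.
#' @export
fit_enterotypes <- function(table, k_max = 10, pseudocount = 1e-6,
                            seed = 1L, low_biomass_threshold = 0,
                            n_splits = 20) {
  stopifnot(inherits(table, "count_table"))
  part <- flag_low_biomass(table, low_biomass_threshold)
  n <- nrow(part$analyzable$counts)
  if (n < 3) stop_("need at least 3 analyzable samples")
  rel <- to_relative(part$analyzable)
  d <- beta_diversity(part$analyzable, "sqrt_jsd", pseudocount = pseudocount)
  k_grid <- 2:min(k_max, n - 1, n %/% 2)
  fits <- lapply(k_grid, function(k) pam_cluster(d, k))
  ch <- vapply(seq_along(k_grid),
               function(i) ch_index(d, fits[[i]]$labels), numeric(1))
  sil <- vapply(seq_along(k_grid),
                function(i) silhouette_width(d, fits[[i]]$labels),
                numeric(1))
  ps <- vapply(seq_along(k_grid), function(i) {
    prediction_strength(d, k_grid[i], n_splits = n_splits,
                        seed = derive_seed(seed, k_grid[i]))
  }, numeric(1))
  best <- which.max(ch)  # ties -> smallest k (which.max takes the first)
  chosen_k <- k_grid[best]
  fit <- fits[[best]]
  drivers <- driver_genera(rel, fit$labels)
  labels_full <- setNames(rep.int(chosen_k + 1L, nrow(table$counts)),
                          rownames(table$counts))
  labels_full[names(fit$labels)] <- fit$labels
  has_low <- length(part$flagged) > 0
  structure(list(
    k_grid = k_grid, ch_index = ch, mean_silhouette = sil,
    prediction_strength = ps, chosen_k = chosen_k,
    labels = if (has_low) labels_full else fit$labels,
    medoids = fit$medoids,
    driver_genus = drivers,
    low_biomass_class = if (has_low) chosen_k + 1L else NA_integer_,
    low_biomass_samples = part$flagged,
    dist = d, rel_abundance = rel,
    params = list(k_max = k_max, pseudocount = pseudocount, seed = seed,
                  low_biomass_threshold = low_biomass_threshold,
                  n_splits = n_splits)),
    class = "enterotype_fit")
}

#' @export
print.enterotype_fit <- function(x, ...) {
  n_low <- length(x$low_biomass_samples)
  cat(sprintf("enterotype_fit: %d samples, chosen k = %d%s\n",
              length(x$labels), x$chosen_k,
              if (n_low > 0)
                sprintf(" (+1 low-biomass class of %d)", n_low) else ""))
  sizes <- table(x$labels[x$labels <= x$chosen_k])
  for (g in seq_len(x$chosen_k)) {
    cat(sprintf("  cluster %d: n = %d, driver = %s, medoid = %s\n",
                g, sizes[as.character(g)], x$driver_genus[g], x$medoids[g]))
  }
  invisible(x)
}

#' @export
summary.enterotype_fit <- function(object, ...) {
  df <- data.frame(k = object$k_grid, ch_index = object$ch_index,
                   mean_silhouette = object$mean_silhouette,
                   prediction_strength = object$prediction_strength)
  df$chosen <- df$k == object$chosen_k
  structure(list(indices = df, chosen_k = object$chosen_k,
                 driver_genus = object$driver_genus,
                 low_biomass = object$low_biomass_samples),
            class = "summary.enterotype_fit")
}

#' @export
print.summary.enterotype_fit <- function(x, ...) {
  cat("Cluster-number selection (argmax Calinski-Harabasz):\n")
  print(x$indices, row.names = FALSE, digits = 4)
  cat(sprintf("chosen k = %d; drivers: %s\n", x$chosen_k,
              paste(x$driver_genus, collapse = ", ")))
  if (length(x$low_biomass) > 0) {
    cat(sprintf("low-biomass class: %d samples\n", length(x$low_biomass)))
  }
  invisible(x)
}

#' Biplot of an enterotype fit
#'
#' Principal-coordinates projection of the clustering distance matrix with
#' samples colored by cluster and medoids marked.
#'
#' @param x an `enterotype_fit`.
#' @param ... passed to [graphics::plot()].
#' @return The ordination, invisibly.
#' @export
plot.enterotype_fit <- function(x, ...) {
  ord <- pcoa(x$dist, n_axes = 2)
  labs <- x$labels[rownames(ord$points)]
  graphics::plot(ord$points, col = labs, pch = 19,
                 xlab = sprintf("PCo1 (%.1f%%)", 100 * ord$prop_explained[1]),
                 ylab = sprintf("PCo2 (%.1f%%)", 100 * ord$prop_explained[2]),
                 ...)
  med <- ord$points[x$medoids, , drop = FALSE]
  graphics::points(med, pch = 4, cex = 2)
  invisible(ord)
}
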