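# Principal coordinates analysis and envfit-style driver-genus vectors.

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: Gower double-centering of `-d^2/2` followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Semi-metric inputs such as
#' Bray-Curtis can produce negative eigenvalues; those axes are dropped and
#' their magnitudes reported, with no Cailliez/Lingoes correction. Axis
#' signs are fixed by forcing each axis's largest-magnitude coordinate
#' positive, so ordinations are reproducible.
#'
#' @param dist a `dist` object over at least 3 samples.
#' @param n_axes number of axes to return (default 2; truncated with a
#'   warning record if fewer positive eigenvalues exist).
#' @return An object of class `pcoa_result`: `points` (n x m coordinates),
#'   `eigenvalues` (all, decreasing), `prop_explained` (per returned axis,
#'   over the positive eigenvalues), `negative_eigenvalues`, `warnings`.
#' @export
pcoa <- function(dist, n_axes = 2) {
  n <- attr(dist, "Size")
  if (is.null(n)) stop_("dist must be a 'dist' object")
  if (n < 3) stop_("need at least 3 samples")
  sc <- suppressWarnings(cmdscale(dist, k = n - 1, eig = TRUE))
  eig <- sc$eig
  tol <- sqrt(.Machine$double.eps) * max(abs(eig), 1)
  n_pos <- sum(eig > tol)
  warnings <- character(0)
  if (n_axes > n_pos) {
    warnings <- sprintf(
      "requested %d axes but only %d positive eigenvalues; truncated",
      n_axes, n_pos)
    n_axes <- n_pos
  }
  pts <- sc$points[, seq_len(n_axes), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive on each axis
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- attr(dist, "Labels")
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts,
                 eigenvalues = eig,
                 prop_explained = eig[seq_len(n_axes)] / sum(eig[eig > tol]),
                 negative_eigenvalues = eig[eig < -tol],
                 warnings = warnings),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa: %d samples, %d axes (%.1f%% of positive inertia)\n",
              nrow(x$points), ncol(x$points),
              100 * sum(x$prop_explained)))
  if (length(x$negative_eigenvalues) > 0) {
    cat(sprintf("  %d negative eigenvalues (largest magnitude %.3g)\n",
                length(x$negative_eigenvalues),
                max(abs(x$negative_eigenvalues))))
  }
  invisible(x)
}

#' Fit variable vectors onto an ordination
#'
#' For each continuous variable (typically a driver genus's relative
#' abundance), regresses the variable on the ordination axes via
#' [vegan::envfit()]: the fitted arrow is the unit direction of steepest
#' increase, `r2` its squared multiple correlation, and significance comes
#' from permuting the variable across samples with the add-one convention
#' (`p >= 1 / (n_perm + 1)`). Zero-variance variables are flagged and
#' excluded.
#'
#' @param ord a [pcoa()] result (or any matrix of sample coordinates).
#' @param variables data frame or matrix of continuous columns, rows
#'   aligned to the ordination samples.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return A data frame, one row per fitted variable: direction components,
#'   `r2` and `p_value`; skipped constant variables in
#'   `attr(, "excluded")`.
#' @export
envfit_vectors <- function(ord, variables, n_perm = 999, seed = 1L) {
  pts <- if (inherits(ord, "pcoa_result")) ord$points else as.matrix(ord)
  vars <- as.data.frame(variables)
  if (nrow(vars) != nrow(pts)) stop_("variables not aligned to ordination")
  const <- vapply(vars, function(v) var(v) == 0, logical(1))
  excluded <- names(vars)[const]
  vars <- vars[, !const, drop = FALSE]
  if (ncol(vars) == 0) stop_("no non-constant variables to fit")
  ef <- with_seed(seed,
                  vegan::envfit(pts, vars, permutations = n_perm))
  arrows <- ef$vectors$arrows
  out <- data.frame(variable = rownames(arrows), arrows,
                    r2 = as.numeric(ef$vectors$r),
                    p_value = as.numeric(ef$vectors$pvals),
                    row.names = NULL, check.names = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "n_perm") <- n_perm
  out
}
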