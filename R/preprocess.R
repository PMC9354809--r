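# Count-table preprocessing: the filters applied between raw genus/OTU
# counts and the diversity / enterotyping stages. Pipeline order is
# filter_rare_taxa -> rarefy: the rare-taxon filter operates on the
# unrarefied totals, rarefaction afterwards (the two do not commute).

#' Remove rare taxa by whole-dataset relative abundance
#'
#' Drops taxa whose total count over all samples is strictly less than
#' `min_fraction` of the grand total (default 0.005%). Ties at the threshold
#' are retained. The sample set is unchanged.
#'
#' @param table a [count_table].
#' @param min_fraction fraction of the grand total in \[0, 1\].
#' @return A [count_table] with the surviving taxa.
#' @export
filter_rare_taxa <- function(table, min_fraction = 5e-5) {
  stopifnot(inherits(table, "count_table"))
  if (min_fraction < 0 || min_fraction > 1) {
    stop_("min_fraction must lie in [0, 1]")
  }
  totals <- colSums(table$counts)
  grand <- sum(as.numeric(totals))
  keep <- totals >= min_fraction * grand
  count_table(table$counts[, keep, drop = FALSE],
              taxonomy = table$taxonomy[names(table$taxonomy) %in%
                                          colnames(table$counts)[keep]])
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples whose total falls below `depth` are excluded and reported
#' via the `"excluded"` attribute. Deterministic per seed.
#'
#' @param table a [count_table].
#' @param depth target depth, or `"min"` for the smallest sample total.
#' @param seed integer seed.
#' @return A rarefied [count_table]; `attr(, "excluded")` lists dropped
#'   sample ids.
#' @export
rarefy <- function(table, depth = "min", seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  totals <- rowSums(table$counts)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth < 1) stop_("depth must be >= 1")
  keep <- totals >= depth
  if (!any(keep)) stop_("rarefaction depth %d exceeds every sample", depth)
  sub <- table$counts[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(sub, 1, function(row) {
      if (sum(row) == depth) return(as.integer(row))
      reads <- rep.int(seq_along(row), row)
      tabulate(reads[sample.int(length(reads), depth)],
               nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(sub)
  res <- count_table(out, taxonomy = table$taxonomy)
  attr(res, "excluded") <- rownames(table$counts)[!keep]
  res
}

#' Aggregate taxa to a higher level (e.g. OTU to genus)
#'
#' Sums counts within groups given a taxon-to-group map. Taxa missing from
#' the map fall into an `unclassified` bucket. The grand total is conserved.
#'
#' @param table a [count_table].
#' @param level_map named character vector, taxon id to group label;
#'   defaults to the table's own taxonomy.
#' @param unclassified label for unmapped taxa.
#' @return A [count_table] over the group labels.
#' @export
aggregate_taxa <- function(table, level_map = table$taxonomy,
                           unclassified = "unclassified") {
  stopifnot(inherits(table, "count_table"))
  if (is.null(level_map)) stop_("no taxonomy map available")
  groups <- level_map[colnames(table$counts)]
  groups[is.na(groups)] <- unclassified
  glev <- unique(unname(groups))
  out <- vapply(glev, function(g) {
    as.integer(rowSums(table$counts[, groups == g, drop = FALSE]))
  }, integer(nrow(table$counts)))
  out <- matrix(out, nrow = nrow(table$counts),
                dimnames = list(rownames(table$counts), glev))
  count_table(out, taxonomy = setNames(glev, glev))
}

#' Convert counts to relative abundances
#'
#' @param table a [count_table]; every sample total must be positive.
#' @return A numeric matrix of row-normalized fractions (class
#'   `rel_abundance`), rows summing to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "count_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0)) {
    stop_("sample '%s' has zero reads; cannot form relative abundances",
          rownames(table$counts)[which(totals == 0)[1]])
  }
  out <- table$counts / totals
  class(out) <- c("rel_abundance", class(out))
  out
}

#' Partition samples into analyzable and low-biomass sets
#'
#' Samples whose read total is strictly below `threshold` are flagged as the
#' non-amplifiable (low bacterial load) class: excluded from clustering but
#' retained for enterotype-membership cross-tabulations.
#'
#' @param table a [count_table].
#' @param threshold read-count threshold (`>= 0`).
#' @return A list: `analyzable` ([count_table]), `flagged` (sample ids).
#' @export
flag_low_biomass <- function(table, threshold = 0) {
  stopifnot(inherits(table, "count_table"))
  if (threshold < 0) stop_("threshold must be >= 0")
  totals <- rowSums(table$counts)
  low <- totals < threshold
  list(analyzable = count_table(table$counts[!low, , drop = FALSE],
                                taxonomy = table$taxonomy),
       flagged = rownames(table$counts)[low])
}

#' Prevalence/abundance filter for differential-abundance testing
#'
#' Keeps taxa whose relative abundance reaches `abundance_cut` in at least a
#' `prevalence_cut` fraction of samples.
#'
#' @param table a [count_table].
#' @param abundance_cut relative-abundance threshold in \[0, 1\]
#'   (default 0.001).
#' @param prevalence_cut fraction of samples in \[0, 1\] (default 0.01).
#' @return A filtered [count_table].
#' @export
prevalence_filter_da <- function(table, abundance_cut = 0.001,
                                 prevalence_cut = 0.01) {
  stopifnot(inherits(table, "count_table"))
  if (abundance_cut < 0 || abundance_cut > 1 ||
      prevalence_cut < 0 || prevalence_cut > 1) {
    stop_("cuts must lie in [0, 1]")
  }
  totals <- rowSums(table$counts)
  rel <- table$counts / pmax(totals, 1)
  prev <- colMeans(rel >= abundance_cut)
  keep <- if (prevalence_cut == 0) rep(TRUE, ncol(rel)) else
    prev >= prevalence_cut
  # a taxon absent everywhere is dropped for any positive cut pair
  if (abundance_cut > 0 && prevalence_cut > 0) {
    keep <- keep & colSums(table$counts) > 0
  }
  count_table(table$counts[, keep, drop = FALSE],
              taxonomy = table$taxonomy[names(table$taxonomy) %in%
                                          colnames(table$counts)[keep]])
}
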