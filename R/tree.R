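#' Read a rooted phylogenetic tree from a newick file
#'
#' Wraps [ape::read.tree()] with the validation UniFrac needs: unique leaf
#' labels and non-negative branch lengths. Absent branch lengths are treated
#' as zero.
#'
#' @param path newick file containing a single tree.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop_("newick parse error in '%s': %s",
                                           path, conditionMessage(e)))
  if (is.null(tr)) stop_("newick parse error in '%s'", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop_("not a phylogenetic tree")
  if (anyDuplicated(tr$tip.label)) {
    stop_("duplicate leaf label '%s'",
          tr$tip.label[anyDuplicated(tr$tip.label)])
  }
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) stop_("negative branch length")
  tr
}
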