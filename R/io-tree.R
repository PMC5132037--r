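#' Read a rooted phylogeny with branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()].  The tree must be
#' a single rooted topology with labelled tips and a branch length on
#' every edge; offending tips/edges are listed in the error message.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo"))
    stop("file contains ", length(tree), " trees; exactly one expected")
  if (is.null(tree)) stop("could not parse a tree from ", path)
  validate_phylogeny(tree)
  tree
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  bad_tips <- which(is.na(tree$tip.label) | !nzchar(tree$tip.label))
  if (length(bad_tips))
    stop("unlabeled tips at positions: ", paste(bad_tips, collapse = ", "))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  bad_edge <- which(is.na(tree$edge.length))
  if (length(bad_edge)) {
    ends <- tree$edge[bad_edge, 2L]
    lab <- ifelse(ends <= length(tree$tip.label),
                  tree$tip.label[ends], paste0("node", ends))
    stop("missing branch lengths on edges to: ",
         paste(lab, collapse = ", "))
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  invisible(tree)
}

#' Write a phylogeny to Newick
#'
#' Writes with enough digits that a read/write round trip preserves
#' branch lengths to better than 1e-12.
#'
#' @param tree an [ape::phylo] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}
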