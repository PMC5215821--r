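#' Parse and write Newick trees
#'
#' Validated wrappers around ape's Newick reader/writer. Trees are ape
#' `phylo` objects throughout the package; branch lengths are expected
#' substitutions per site.
#'
#' @param text A Newick string.
#' @param tree An ape `phylo` object.
#' @return `parse_newick()`: a `phylo`; `write_newick()`: a Newick string.
#' @export
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
#' write_newick(tr)
parse_newick <- function(text) {
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (opens != closes) {
    stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'", opens, closes))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick string")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' @rdname parse_newick
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

# Number of free branch lengths of an unrooted binary tree on n taxa; a
# rooted binary input is counted as its unrooted equivalent (2n - 3).
n_free_branches <- function(tree) {
  n <- length(tree$tip.label)
  if (n == 1L) return(0L)
  if (n == 2L) return(1L)
  2L * n - 3L
}

#' Join two trees by a connecting branch
#'
#' Builds the single-phylogeny (common ancestry) topology from two group
#' trees: the two subtree roots are connected by a branch of total length
#' `t`, split across the two root edges (placement along the branch is
#' immaterial for likelihoods under reversibility).
#'
#' @param tree_a,tree_b `phylo` objects with disjoint leaf sets.
#' @param t Total connecting branch length.
#' @return A rooted `phylo` on the union of the leaves.
#' @export
join_trees <- function(tree_a, tree_b, t) {
  if (length(intersect(tree_a$tip.label, tree_b$tip.label)) > 0) {
    stop("leaf sets overlap")
  }
  na <- sub(";$", "", write_newick(tree_a))
  nb <- sub(";$", "", write_newick(tree_b))
  parse_newick(sprintf("(%s:%.10g,%s:%.10g);", na, t / 2, nb, t / 2))
}

# Stand-in balanced quartet ((A:b,B:b):i,(C:d,D:d):i); used by the presets.
standin_quartet <- function(labels, terminal = 0.4, internal = 0.2) {
  stopifnot(length(labels) == 4L)
  parse_newick(sprintf("((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g);",
                       labels[1], terminal, labels[2], terminal, internal,
                       labels[3], terminal, labels[4], terminal, internal))
}
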