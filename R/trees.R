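#' Read and validate a rooted binary phylogeny
#'
#' Reads a tree from a Newick or NEXUS source and checks the invariants the
#' IE algorithm and its comparators rely on: the tree is rooted and fully
#' resolved (every internal node has exactly two children) and every branch
#' has a strictly positive, finite length. NEXUS `TRANSLATE` blocks are
#' honoured; if a NEXUS file contains several trees only the first is used.
#'
#' Node numbering follows the `"phylo"` convention: tips are `1..n` (in the
#' order of `tip.label`), the root is `n + 1`, and branches are identified by
#' their child node throughout this package.
#'
#' @param file path to a Newick or NEXUS file. Exactly one of `file` and
#'   `text` must be given.
#' @param text a Newick or NEXUS string.
#' @return An object of class `"phylo"` passing [validate_phylogeny()].
#' @examples
#' tr <- read_tree(text = "((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
read_tree <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' or 'text'")
  src <- if (is.null(text)) readLines(file, warn = FALSE) else text
  is_nexus <- any(grepl("^\\s*#NEXUS", src, ignore.case = TRUE))
  tr <- if (is_nexus) {
    out <- if (is.null(text)) ape::read.nexus(file) else
      ape::read.nexus(textConnection(text))
    if (inherits(out, "multiPhylo")) out[[1L]] else out
  } else {
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("could not parse a tree from the input")
  validate_phylogeny(tr)
}

#' Validate the invariants of a study phylogeny
#'
#' @param tree a `"phylo"` object.
#' @return `tree`, invisibly unchanged, if all checks pass; otherwise an
#'   error naming the offending node.
#' @export
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  n <- ape::Ntip(tree)
  if (n < 2L) stop("tree must have at least 2 tips")
  tab <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)
  poly <- which(tab > 2L)
  if (length(poly))
    stop("polytomy at internal node(s): ", paste(poly, collapse = ", "))
  unary <- which(tab == 1L)
  if (length(unary))
    stop("unary internal node(s): ", paste(unary, collapse = ", "))
  bad <- which(!is.finite(tree$edge.length) | tree$edge.length <= 0)
  if (length(bad))
    stop("non-positive or non-finite branch length above node(s): ",
         paste(tree$edge[bad, 2L], collapse = ", "))
  if (tree$Nnode != n - 1L)
    stop("expected ", n - 1L, " internal nodes for ", n, " tips, found ",
         tree$Nnode)
  tree
}

#' Path distance between two nodes
#'
#' Sum of branch lengths along the unique path joining two nodes, in the
#' tree's time units.
#'
#' @param tree a validated `"phylo"` object.
#' @param from,to node numbers.
#' @return A single non-negative number.
#' @examples
#' tr <- read_tree(text = "((A:1,B:1):1,C:2);")
#' path_distance(tr, 1, 3)  # tip A to tip C: 1 + 1 + 2
#' @export
path_distance <- function(tree, from, to) {
  nn <- ape::Ntip(tree) + tree$Nnode
  if (!all(c(from, to) %in% seq_len(nn)))
    stop("unknown node id: ", paste(setdiff(c(from, to), seq_len(nn)),
                                    collapse = ", "))
  unname(ape::dist.nodes(tree)[from, to])
}

#' Nodes ordered by distance from the root
#'
#' @param tree a validated `"phylo"` object.
#' @return A data frame with columns `node` and `depth` (root-to-node path
#'   distance), sorted by non-decreasing depth; ties keep node-number order.
#' @export
depth_order <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  out <- data.frame(node = seq_along(d), depth = d)
  out <- out[order(out$depth, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-branch table of a phylogeny
#'
#' Internal helper shared by the reconstruction and simulation code: one row
#' per branch, identified by the child node.
#'
#' @noRd
branch_table <- function(tree) {
  data.frame(branch = tree$edge[, 2L],
             parent = tree$edge[, 1L],
             child  = tree$edge[, 2L],
             length = tree$edge.length)
}
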