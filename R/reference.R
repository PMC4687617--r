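#' PIC ancestral states (local pruning-pass estimates)
#'
#' Felsenstein's pruning pass run tipward to rootward: at each internal node
#' the value is the inverse-adjusted-branch-length weighted mean of its two
#' daughters, and the node's own branch to its parent is lengthened by
#' `b_L b_R / (b_L + b_R)`. Each value is the local maximum-likelihood
#' estimate of the node's state under Brownian motion given its descendants.
#' Implemented with [ape::ace()] (`method = "pic"`), which returns exactly
#' these estimates.
#'
#' @param tree a validated `"phylo"` object.
#' @param log_tips named numeric vector of tip values in log space.
#' @return Named numeric vector of `n - 1` internal-node values
#'   (names are node numbers, root first).
#' @export
pic_ancestral_states <- function(tree, log_tips) {
  validate_phylogeny(tree)
  x <- log_tips[tree$tip.label]
  if (any(is.na(x))) stop("missing tip value(s)")
  ape::ace(unname(x), tree, type = "continuous", method = "pic")$ace
}

#' Phylogenetically independent contrasts
#'
#' Standardized contrasts between sister lineages, one per internal node
#' (`n - 1` in total), via [ape::pic()].
#'
#' @inheritParams pic_ancestral_states
#' @return A data frame of class `"branch_changes"` with columns `node` and
#'   `contrast`, plus attribute `method = "PIC"`.
#' @export
pic_contrasts <- function(tree, log_tips) {
  validate_phylogeny(tree)
  x <- log_tips[tree$tip.label]
  if (any(is.na(x))) stop("missing tip value(s)")
  ct <- ape::pic(unname(x), tree)
  n <- ape::Ntip(tree)
  out <- data.frame(node = (n + 1L):(n + tree$Nnode),
                    contrast = unname(ct))
  structure(out, method = "PIC", class = c("branch_changes", "data.frame"))
}

#' Partially independent directional contrasts (PIDC)
#'
#' Ancestor-to-descendant standardized contrasts for every branch of the
#' tree: `(child - parent) / sqrt(branch length)`, with internal-node values
#' taken from [pic_ancestral_states()] and tip values observed. Produces
#' `2n - 2` contrasts; unlike PIC these are only partially independent, but
#' under Brownian motion they are unbiased estimates of the per-branch
#' standardized changes.
#'
#' @inheritParams pic_ancestral_states
#' @return A data frame of class `"branch_changes"` with columns `branch`
#'   (= child node), `parent`, `child`, `length`, `contrast`, `depth`;
#'   attribute `method = "PIDC"`.
#' @export
pidc_contrasts <- function(tree, log_tips) {
  validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  anc <- pic_ancestral_states(tree, log_tips)
  vals <- c(unname(log_tips[tree$tip.label]), unname(anc))
  br <- branch_table(tree)
  br$contrast <- (vals[br$child] - vals[br$parent]) / sqrt(br$length)
  br$depth <- ape::node.depth.edgelength(tree)[br$child]
  structure(br, method = "PIDC", class = c("branch_changes", "data.frame"))
}

#' Vertex-to-centroid distances of a triangle (Apollonius)
#'
#' The correct geometry that the Farris formulas were mistaken for: the
#' median from a vertex has length `sqrt(2 b^2 + 2 c^2 - a^2) / 2` (with `a`
#' the opposite side), and the centroid lies 2/3 of the way along it, so the
#' vertex-to-centroid distance is `sqrt(2 b^2 + 2 c^2 - a^2) / 3`.
#'
#' @param a,b,c side lengths satisfying the triangle inequality
#'   (degenerate/collinear triangles allowed).
#' @return Numeric vector `c(A = , B = , C = )` of distances from the
#'   vertices opposite sides `a`, `b`, `c`.
#' @examples
#' centroid_distances(1, 1, 1)  # all 1/sqrt(3)
#' @export
centroid_distances <- function(a, b, c) {
  if (any(c(a, b, c) < 0)) stop("side lengths must be non-negative")
  rad <- c(A = 2 * b^2 + 2 * c^2 - a^2,
           B = 2 * a^2 + 2 * c^2 - b^2,
           C = 2 * a^2 + 2 * b^2 - c^2)
  if (any(rad < -1e-12 * max(a, b, c, 1)^2))
    stop("side lengths violate the triangle inequality")
  sqrt(pmax(rad, 0)) / 3
}

#' Centroid distances for the IE triangle
#'
#' Convenience wrapper mapping the IE triangle's side labels to
#' [centroid_distances()]: `S1` joins the two descendants, `S2` joins
#' descendant 2 to the adaptive-peak vertex, `S3` joins descendant 1 to the
#' peak vertex, so descendant 1 is opposite `S2`, descendant 2 opposite
#' `S3`, and the peak vertex opposite `S1`.
#'
#' @param S1,S2,S3 IE triangle side lengths.
#' @return Numeric vector `c(T1 = , T2 = , T3 = )`: true centroid distances
#'   from descendant 1, descendant 2, and the adaptive-peak vertex.
#' @examples
#' round(apollonius_centroid_distances(1.2, 0.24, 1.04), 2)
#' @export
apollonius_centroid_distances <- function(S1, S2, S3) {
  d <- centroid_distances(S2, S3, S1)
  stats::setNames(d, c("T1", "T2", "T3"))
}
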