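# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Felsenstein pruning pass written from first principles: returns the local
# ancestral estimates and the adjusted branch lengths, indexed by node.
prune_oracle <- function(tree, log_tips) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  vals <- c(unname(log_tips[tree$tip.label]), rep(NA_real_, tree$Nnode))
  blen <- rep(NA_real_, nn)
  blen[tree$edge[, 2L]] <- tree$edge.length
  depth <- ape::node.depth.edgelength(tree)
  internal <- (n + 1L):nn
  for (v in internal[order(-depth[internal])]) {
    ch <- tree$edge[tree$edge[, 1L] == v, 2L]
    bl <- blen[ch[1L]]; br <- blen[ch[2L]]
    vals[v] <- (vals[ch[1L]] / bl + vals[ch[2L]] / br) / (1 / bl + 1 / br)
    if (v != n + 1L) blen[v] <- blen[v] + bl * br / (bl + br)
  }
  list(values = vals[internal], nodes = internal)
}

# Planar-embedding oracle for vertex-to-centroid distances: place the
# triangle in coordinates via the law of cosines, take the centroid, and
# measure Euclidean distances. Sides (a, b, c) opposite vertices (A, B, C).
centroid_oracle <- function(a, b, c) {
  # B at origin, C at (a, 0); A from sides c (A-B) and b (A-C)
  x <- (a^2 + c^2 - b^2) / (2 * a)
  y2 <- c^2 - x^2
  A <- c(x, sqrt(max(y2, 0)))
  B <- c(0, 0)
  C <- c(a, 0)
  G <- (A + B + C) / 3
  c(A = sqrt(sum((A - G)^2)),
    B = sqrt(sum((B - G)^2)),
    C = sqrt(sum((C - G)^2)))
}

# Random side lengths guaranteed to satisfy the triangle inequality:
# generated from random planar points, so validity is by construction.
random_triangle_sides <- function() {
  p <- matrix(stats::runif(6, -1, 1), ncol = 2)
  c(a = sqrt(sum((p[2, ] - p[3, ])^2)),
    b = sqrt(sum((p[1, ] - p[3, ])^2)),
    c = sqrt(sum((p[1, ] - p[2, ])^2)))
}
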