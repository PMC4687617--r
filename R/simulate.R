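#' Simulate a surrogate study tree
#'
#' Draws a rooted binary pure-birth tree and (by default) rescales it to unit
#' root-to-tip height, the normalisation used throughout the simulation
#' experiments so that a Brownian rate of 1 yields unit log-trait variance at
#' the tips.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed; the same seed always yields the same tree.
#' @param height target root-to-tip height, or `NULL` to keep the raw
#'   pure-birth branch lengths.
#' @return A validated `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, seed = 1L, height = 1) {
  if (n_tips < 2L) stop("n_tips must be at least 2")
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * (height / h)
  }
  validate_phylogeny(tr)
}

#' Simulate one geometrically normal trait under Brownian motion
#'
#' Evolution proceeds in log space: the change along each branch is an
#' independent draw from Normal(0, `sigma2` * branch length), node values are
#' the running sums from `root_value` down the tree, and arithmetic-scale
#' values are obtained by exponentiation at every node and tip. Recording the
#' per-branch increments gives exact ground truth for branch-specific change,
#' which tip-level multivariate-normal simulation would not.
#'
#' @param tree a validated `"phylo"` object.
#' @param sigma2 Brownian rate (log-trait^2 per unit branch length), > 0.
#' @param root_value log-trait value at the root.
#' @param seed integer seed.
#' @return An object of class `"bm_truth"`: a list with elements
#'   \describe{
#'     \item{tree}{the input tree}
#'     \item{log_values}{numeric, one value per node (tips then internals)}
#'     \item{arithmetic_values}{`exp(log_values)`}
#'     \item{tips}{named tip vector on the arithmetic scale, ready for
#'       [ie_reconstruct()]}
#'     \item{log_tips}{named tip vector in log space, ready for PIC/PIDC}
#'     \item{branch}{data frame: branch (child node), parent, child, length,
#'       change (log child - log parent), std_change (change / sqrt(length))}
#'     \item{sigma2, root_value, seed}{the simulation settings}
#'   }
#' @examples
#' tr <- simulate_tree(10, seed = 1)
#' tru <- simulate_bm_trait(tr, sigma2 = 1, seed = 7)
#' all.equal(log(tru$arithmetic_values), tru$log_values)
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root_value = 0, seed = 1L) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  set.seed(seed)
  incr <- stats::rnorm(nrow(tree$edge), mean = 0,
                       sd = sqrt(sigma2 * tree$edge.length))
  .bm_truth_from_increments(tree, incr, sigma2, root_value, seed)
}

# Accumulate per-branch log increments into node values (root-to-tip pass).
.bm_truth_from_increments <- function(tree, incr, sigma2, root_value, seed) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  root <- n + 1L
  vals <- rep(NA_real_, nn)
  vals[root] <- root_value
  # preorder over edges: parents always appear before their children
  ord <- ape::reorder.phylo(tree, "cladewise")
  eo <- match(paste(ord$edge[, 1L], ord$edge[, 2L]),
              paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (k in eo)
    vals[tree$edge[k, 2L]] <- vals[tree$edge[k, 1L]] + incr[k]
  br <- branch_table(tree)
  br$change <- vals[br$child] - vals[br$parent]
  br$std_change <- br$change / sqrt(br$length)
  tips <- exp(vals[seq_len(n)])
  names(tips) <- tree$tip.label
  log_tips <- vals[seq_len(n)]
  names(log_tips) <- tree$tip.label
  structure(list(tree = tree,
                 log_values = vals,
                 arithmetic_values = exp(vals),
                 tips = tips,
                 log_tips = log_tips,
                 branch = br,
                 sigma2 = sigma2, root_value = root_value, seed = seed),
            class = "bm_truth")
}

#' Simulate a pair of traits under correlated Brownian motion
#'
#' Both traits evolve in log space with unit rate and per-unit-length
#' increment covariance `beta`, i.e. rate matrix `[[1, beta], [beta, 1]]`
#' scaled by branch length. Because trait 1 has unit rate, `beta` is exactly
#' the evolutionary regression coefficient of trait 2 on trait 1.
#'
#' @param tree a validated `"phylo"` object.
#' @param beta evolutionary regression coefficient in `[0, 1]`.
#' @param root_value shared log-trait root value.
#' @param seed integer seed.
#' @return An object of class `"pair_truth"`: list with `trait1` and
#'   `trait2` (each a `"bm_truth"` sharing `tree`) and `beta`.
#' @export
simulate_correlated_pair <- function(tree, beta, root_value = 0, seed = 1L) {
  if (!is.finite(beta) || abs(beta) > 1)
    stop("beta must lie in [-1, 1] for a positive semi-definite rate matrix")
  set.seed(seed)
  ne <- nrow(tree$edge)
  sdlen <- sqrt(tree$edge.length)
  e1 <- stats::rnorm(ne, 0, sdlen)
  e2 <- stats::rnorm(ne, 0, sdlen)
  i1 <- e1
  i2 <- beta * e1 + sqrt(1 - beta^2) * e2
  structure(list(
    trait1 = .bm_truth_from_increments(tree, i1, 1, root_value, seed),
    trait2 = .bm_truth_from_increments(tree, i2, 1, root_value, seed),
    beta = beta), class = "pair_truth")
}

#' Evenly spaced evolutionary regression coefficients
#'
#' @param n_pairs number of values (>= 2).
#' @return Numeric vector from 0 to 1 inclusive, length `n_pairs`.
#' @export
beta_grid <- function(n_pairs) {
  if (n_pairs < 2L) stop("n_pairs must be at least 2")
  seq(0, 1, length.out = n_pairs)
}

#' Spawn a reproducible per-replicate seed from a master seed
#'
#' Fixed arithmetic (no RNG state involved) so that any single replicate can
#' be re-run in isolation. Results stay below 2^31.
#'
#' @param master integer master seed.
#' @param i replicate index (1-based).
#' @return An integer seed.
#' @export
replicate_seed <- function(master, i) {
  as.integer((as.double(master) + 999983 * as.double(i)) %% 2147483647)
}

#' Write tip trait observations as a two-column table
#'
#' @param tips named numeric vector (tip label, value).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trait_table <- function(tips, file) {
  utils::write.table(data.frame(tip = names(tips), value = unname(tips)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read tip trait observations from a delimited table
#'
#' Expects a header line and two columns: tip label and value.
#'
#' @param file input path.
#' @return Named numeric vector.
#' @export
read_trait_table <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d[[2L]]), as.character(d[[1L]]))
}

#' @export
print.bm_truth <- function(x, ...) {
  cat("Brownian-motion trait simulation (log space)\n")
  cat("  tips:", ape::Ntip(x$tree), " branches:", nrow(x$branch), "\n")
  cat("  sigma2:", x$sigma2, " root log value:", x$root_value,
      " seed:", x$seed, "\n")
  invisible(x)
}
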