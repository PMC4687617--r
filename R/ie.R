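#' The IE proportional distance metric
#'
#' `S = 2 |x - y| / (x + y)`, the proportional distance the IE algorithm uses
#' for triangle side lengths. For positive inputs it is bounded: as the two
#' values diverge it asymptotes at 2, which is the root cause of the
#' method's systematic underestimation of large proportional changes.
#'
#' @param x,y trait values on the arithmetic scale (vectorised).
#' @return Non-negative side length(s); `< 2` for positive inputs.
#' @examples
#' ie_distance(1, 3)      # 1
#' ie_distance(1, 1e9)    # just under the asymptote at 2
#' @export
ie_distance <- function(x, y) {
  s <- x + y
  if (any(s == 0))
    stop("IE distance undefined: x + y = 0 for pair(s) (",
         paste(which(s == 0), collapse = ", "), ")")
  2 * abs(x - y) / s
}

#' Log-difference distance
#'
#' `|ln x - ln y|`, the unbiased measure of proportional distance that the
#' modified IE variant substitutes for [ie_distance()]. Unbounded, zero only
#' when `x == y`.
#'
#' @param x,y strictly positive trait values (vectorised).
#' @return Non-negative distance(s).
#' @export
log_distance <- function(x, y) {
  if (any(x <= 0) || any(y <= 0))
    stop("log distance requires strictly positive values")
  abs(log(x) - log(y))
}

#' Adaptive peak of an internal node
#'
#' The tree-wide inverse-path-distance weighted mean of all tip values:
#' `AP = sum(x_i / d_i) / sum(1 / d_i)` with `d_i` the branch-path distance
#' from tip `i` to the node. This extends Felsenstein's two-tip ancestor
#' formula to the whole tree and is computed from the original
#' (untransformed) tip values before any traversal.
#'
#' @param tree a validated `"phylo"` object.
#' @param tips named numeric vector of tip values (names = tip labels).
#' @param node internal node number.
#' @return The adaptive peak, in the units of `tips`; always within the
#'   range of the tip values.
#' @export
adaptive_peak <- function(tree, tips, node) {
  n <- ape::Ntip(tree)
  if (node <= n || node > n + tree$Nnode)
    stop("node ", node, " is not an internal node")
  x <- tips[tree$tip.label]
  if (any(is.na(x))) stop("missing tip value(s): ",
                          paste(tree$tip.label[is.na(x)], collapse = ", "))
  d <- ape::dist.nodes(tree)[seq_len(n), node]
  if (any(d == 0)) stop("tip at zero path distance from node ", node)
  sum(x / d) / sum(1 / d)
}

# All adaptive peaks at once: weight matrix W (internal nodes x tips) with
# rows 1/d normalised to sum 1, so AP = W %*% x. O(n^2) once per tree.
.ap_weights <- function(tree) {
  n <- ape::Ntip(tree)
  D <- ape::dist.nodes(tree)[seq_len(n), (n + 1L):(n + tree$Nnode),
                             drop = FALSE]
  W <- t(1 / D)
  W / rowSums(W)
}

#' Farris vertex-to-centroid distances
#'
#' The quantity IE uses in place of true centroid distances: at each vertex,
#' the sum of the two incident sides minus the opposite side, halved. Side
#' labels follow the IE triangle: `S1` joins the two descendants, `S2` joins
#' descendant 2 to the adaptive-peak vertex, `S3` joins descendant 1 to the
#' peak vertex. `T1`/`T2`/`T3` attach to descendant 1 / descendant 2 / the
#' peak vertex respectively. Negative values are arithmetically possible and
#' are returned as-is (the reconstruction layer flags them).
#'
#' @param S1,S2,S3 non-negative side lengths (vectorised).
#' @return A list with components `T1`, `T2`, `T3`.
#' @examples
#' farris_T(1.2, 0.24, 1.04)  # T1 = 1.0, T2 = 0.2, T3 = 0.04
#' @export
farris_T <- function(S1, S2, S3) {
  list(T1 = (S1 + S3 - S2) / 2,
       T2 = (S1 + S2 - S3) / 2,
       T3 = (S2 + S3 - S1) / 2)
}

#' Branch-length-scaled R-values
#'
#' `R_i = T_i * 2 b_i / (b1 + b2)`: the IE "branch-specific rate of change",
#' a Farris distance rescaled by the branch's share of the cherry's total
#' branch length. With equal branches the scale factor is 1.
#'
#' @param T1,T2 Farris distances for descendants 1 and 2.
#' @param b1,b2 their branch lengths (strictly positive).
#' @return A list with components `R1`, `R2`.
#' @export
r_values <- function(T1, T2, b1, b2) {
  if (any(b1 <= 0) || any(b2 <= 0)) stop("branch lengths must be positive")
  s <- b1 + b2
  list(R1 = T1 * 2 * b1 / s, R2 = T2 * 2 * b2 / s)
}

#' IE ancestral state of a cherry
#'
#' The inverse-R weighted mean of the two descendant values:
#' `A = (x1/R1 + x2/R2) / (1/R1 + 1/R2)`. Undefined when either R-value is
#' zero (which happens whenever two triangle vertices coincide) — the
#' documented failure mode of the method.
#'
#' @param x1,x2 descendant trait values.
#' @param R1,R2 their R-values; must be strictly positive.
#' @return The ancestral state, between `x1` and `x2`.
#' @export
ancestral_state <- function(x1, x2, R1, R2) {
  if (any(R1 <= 0) || any(R2 <= 0))
    stop("ancestral state undefined: R-values must be strictly positive ",
         "(equal vertex values give R = 0)")
  (x1 / R1 + x2 / R2) / (1 / R1 + 1 / R2)
}

#' Fit the Independent Evolution reconstruction to a tree and trait
#'
#' Runs the full IE algorithm: adaptive peaks are precomputed for every
#' internal node from the original tip values, then the tree is traversed
#' from the tips to the root, at each step treating the current cherry's two
#' values and their parent's adaptive peak as triangle vertices, measuring
#' side lengths with the chosen metric, converting them to vertex distances
#' with the Farris formulas, scaling by relative branch length into R-values,
#' and reconstructing the ancestor as the inverse-R weighted mean. The
#' reconstructed value replaces the cherry, which keeps its parent's original
#' branch length, and the traversal continues to the root.
#'
#' `metric = "ie"` is the published algorithm: arithmetic-scale values and
#' the bounded proportional metric [ie_distance()]. `metric = "log"` is the
#' modified variant: values are log-transformed up front (so adaptive peaks
#' are means of logs) and sides are plain differences of logged values,
#' equivalent to [log_distance()] on the arithmetic values.
#'
#' After the traversal, each branch's R-value is signed by the direction of
#' reconstructed change along it, and a log-space standardized directional
#' contrast `(ln child - ln parent) / sqrt(branch length)` is computed for
#' every branch.
#'
#' @param tree a validated `"phylo"` object.
#' @param tips named numeric vector of strictly positive arithmetic-scale
#'   tip values.
#' @param metric `"ie"` (published) or `"log"` (modified variant).
#' @param on_undefined `"error"` (default) stops at the first undefined
#'   ancestral state, naming the node; `"NA"` records `NaN` and continues,
#'   for bulk simulation where rare degenerate draws must not abort a run.
#' @return An object of class `"ie_fit"`: list with
#'   \describe{
#'     \item{node}{data frame, one row per internal node: `node`, `depth`,
#'       `adaptive_peak` and `ancestral_state` (arithmetic scale),
#'       `log_ancestral_state`}
#'     \item{branch}{data frame, one row per branch: `branch` (= child
#'       node), `parent`, `child`, `length`, `S1`, `S2`, `S3`, `T`, `R`,
#'       `signed_R`, `contrast` (log-space standardized directional
#'       contrast), `depth` (root distance of the branch's child)}
#'     \item{metric, n_undefined, tree, call}{bookkeeping}
#'   }
#' @examples
#' tr <- read_tree(text = "((A:8,B:8):3,C:11);")
#' fit <- ie_reconstruct(tr, c(A = 2, B = 8, C = 5))
#' coef(fit)
#' @export
ie_reconstruct <- function(tree, tips, metric = c("ie", "log"),
                           on_undefined = c("error", "NA")) {
  metric <- match.arg(metric)
  on_undefined <- match.arg(on_undefined)
  validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  x <- tips[tree$tip.label]
  if (any(is.na(x)))
    stop("missing tip value(s): ",
         paste(tree$tip.label[!tree$tip.label %in% names(tips)],
               collapse = ", "))
  if (any(x <= 0))
    stop("IE requires strictly positive trait values (negative or zero ",
         "values are a documented failure mode of the metric)")
  x <- unname(x)

  # working scale: arithmetic for "ie", logged for "log"
  work <- if (metric == "log") log(x) else x
  side <- if (metric == "log") function(a, b) abs(a - b) else ie_distance

  ap <- drop(.ap_weights(tree) %*% work)        # indexed by node - n
  depth <- ape::node.depth.edgelength(tree)

  kids <- lapply(seq_len(nn), function(v) which(tree$edge[, 1L] == v))
  vals <- c(work, rep(NA_real_, tree$Nnode))
  internal <- (n + 1L):nn
  ord <- internal[order(-depth[internal], internal)]   # deepest cherry first

  br <- branch_table(tree)
  m <- nrow(br)
  S1v <- S2v <- S3v <- Tv <- Rv <- rep(NA_real_, m)
  n_undef <- 0L

  undef <- function(node, why) {
    if (on_undefined == "error")
      stop("IE reconstruction undefined at node ", node, ": ", why)
    n_undef <<- n_undef + 1L
    NaN
  }

  for (v in ord) {
    e <- kids[[v]]                    # two child edges of v
    c1 <- tree$edge[e[1L], 2L]; c2 <- tree$edge[e[2L], 2L]
    b1 <- tree$edge.length[e[1L]]; b2 <- tree$edge.length[e[2L]]
    x1 <- vals[c1]; x2 <- vals[c2]
    APv <- ap[v - n]
    if (is.na(x1) || is.na(x2)) {            # NaN from a deeper failure
      vals[v] <- NaN
      next
    }
    if (metric == "ie" &&
        (x1 + x2 == 0 || x2 + APv == 0 || x1 + APv == 0)) {
      vals[v] <- undef(v, "a pair of triangle vertices sums to zero")
      next
    }
    s1 <- side(x1, x2); s2 <- side(x2, APv); s3 <- side(x1, APv)
    tt <- farris_T(s1, s2, s3)
    rr <- r_values(tt$T1, tt$T2, b1, b2)
    S1v[e] <- s1; S2v[e] <- s2; S3v[e] <- s3
    Tv[e] <- c(tt$T1, tt$T2); Rv[e] <- c(rr$R1, rr$R2)
    if (rr$R1 <= 0 || rr$R2 <= 0) {
      vals[v] <- undef(v, "non-positive R-value (coincident triangle vertices)")
      next
    }
    vals[v] <- ancestral_state(x1, x2, rr$R1, rr$R2)
  }

  # back to log/arithmetic scales
  log_vals <- if (metric == "log") vals else suppressWarnings(log(vals))
  arith_anc <- if (metric == "log") exp(vals[internal]) else vals[internal]
  arith_ap <- if (metric == "log") exp(ap) else ap

  br$S1 <- S1v; br$S2 <- S2v; br$S3 <- S3v
  br$T <- Tv; br$R <- Rv
  br$signed_R <- Rv * sign(vals[br$child] - vals[br$parent])
  br$contrast <- (log_vals[br$child] - log_vals[br$parent]) / sqrt(br$length)
  br$depth <- depth[br$child]

  node <- data.frame(node = internal,
                     depth = depth[internal],
                     adaptive_peak = unname(arith_ap),
                     ancestral_state = unname(arith_anc),
                     log_ancestral_state = log_vals[internal])

  structure(list(node = node, branch = br, metric = metric,
                 n_undefined = n_undef, tree = tree,
                 call = match.call()),
            class = "ie_fit")
}

#' @export
print.ie_fit <- function(x, ...) {
  n <- ape::Ntip(x$tree)
  cat("Independent Evolution reconstruction (metric: ",
      if (x$metric == "ie") "IE proportional" else "log-difference",
      ")\n", sep = "")
  cat("  ", n, " tips; ", nrow(x$node), " ancestral states; ",
      nrow(x$branch), " branch R-values\n", sep = "")
  if (x$n_undefined > 0L)
    cat("  undefined ancestral states recorded as NaN:", x$n_undefined, "\n")
  root <- x$node[x$node$depth == min(x$node$depth), ]
  cat("  root state: ", format(root$ancestral_state[1L], digits = 6),
      " (adaptive peak ", format(root$adaptive_peak[1L], digits = 6),
      ")\n", sep = "")
  invisible(x)
}

#' @export
summary.ie_fit <- function(object, ...) {
  ans <- list(metric = object$metric,
              n_tips = ape::Ntip(object$tree),
              n_undefined = object$n_undefined,
              anc = summary(object$node$ancestral_state),
              R = summary(object$branch$R),
              signed_R = summary(object$branch$signed_R),
              contrast = summary(object$branch$contrast))
  class(ans) <- "summary.ie_fit"
  ans
}

#' @export
print.summary.ie_fit <- function(x, ...) {
  cat("IE reconstruction summary (", x$n_tips, " tips, metric ",
      x$metric, ")\n", sep = "")
  cat("Ancestral states (arithmetic scale):\n"); print(x$anc)
  cat("Unsigned R-values:\n"); print(x$R)
  cat("Signed R-values:\n"); print(x$signed_R)
  cat("Standardized directional contrasts (log space):\n"); print(x$contrast)
  if (x$n_undefined > 0L) cat("Undefined states (NaN):", x$n_undefined, "\n")
  invisible(x)
}

#' Ancestral states of an IE fit
#'
#' @param object an `"ie_fit"`.
#' @param ... unused.
#' @return Named numeric vector of arithmetic-scale ancestral states,
#'   one per internal node.
#' @export
coef.ie_fit <- function(object, ...) {
  stats::setNames(object$node$ancestral_state, object$node$node)
}

#' Plot branch-specific IE estimates against depth
#'
#' Base-graphics diagnostic: signed R-values (or contrasts) of each branch
#' against the branch's distance from the root.
#'
#' @param x an `"ie_fit"`.
#' @param what `"signed_R"` or `"contrast"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ie_fit <- function(x, what = c("signed_R", "contrast"), ...) {
  what <- match.arg(what)
  graphics::plot(x$branch$depth, x$branch[[what]],
                 xlab = "branch distance from root",
                 ylab = if (what == "signed_R") "signed R-value" else
                   "standardized directional contrast (log space)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
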