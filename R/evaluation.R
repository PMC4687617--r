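#' Ordinary least squares through the origin
#'
#' `slope = sum(x y) / sum(x^2)`, the estimator used for all contrast
#' regressions (contrasts have no defined intercept).
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value in
#'   either are dropped.
#' @return The slope.
#' @export
origin_ols <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 complete pairs")
  sx2 <- sum(x^2)
  if (sx2 == 0) stop("all x are zero: slope undefined")
  sum(x * y) / sx2
}

# Row-wise summary of an estimates-minus-truth matrix (rows = nodes or
# branches, cols = replicates).
.bias_summary <- function(id, depth, bias, est, method) {
  qs <- t(apply(bias, 1L, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE))
  out <- data.frame(id = id, depth = depth, method = method,
                    n = rowSums(is.finite(bias)),
                    mean_bias = rowMeans(bias, na.rm = TRUE),
                    min = qs[, 1L], q25 = qs[, 2L], median = qs[, 3L],
                    q75 = qs[, 4L], max = qs[, 5L],
                    mean_estimate = rowMeans(est, na.rm = TRUE))
  out[order(out$depth, out$id), , drop = FALSE]
}

#' Single-trait bias experiment
#'
#' Replicates the geometric Brownian-motion audit: for each of `n_traits`
#' replicates a log-space BM trait (rate `sigma2`, root log value 0) is
#' simulated on `tree` and exponentiated; IE is fitted to the arithmetic
#' values (its estimates then log-transformed so all comparisons are in log
#' space) and PIDC to the logged values. Per-node and per-branch summaries
#' of estimate minus truth are accumulated, along with the per-branch
#' signed R-values and true changes needed to judge R-values as estimates of
#' branch-specific change.
#'
#' @param tree a validated `"phylo"` object.
#' @param n_traits number of replicate traits.
#' @param sigma2 Brownian rate in log space.
#' @param seed master seed; replicate `i` uses [replicate_seed()]`(seed, i)`.
#' @return An object of class `"bias_experiment"`: list with
#'   \describe{
#'     \item{nodes}{per-node bias summaries (log space), methods `IE` and
#'       `PIDC`, ordered by root distance}
#'     \item{branches}{per-branch summaries of standardized directional
#'       contrasts minus true standardized changes, methods `IE`, `PIDC`,
#'       and `truth` (raw simulated contrasts, bias identically 0)}
#'     \item{rvalues}{list of matrices `signed_R` and `true_change`
#'       (branches x replicates) for [rvalue_accuracy()]}
#'     \item{raw}{replicate-level matrices (rows = nodes or branches,
#'       columns = replicates) of estimates and truths, for significance
#'       tests on any node or branch}
#'     \item{n_undefined}{count of IE replicates containing undefined
#'       (NaN) states}
#'   }
#' @export
single_trait_experiment <- function(tree, n_traits = 1000, sigma2 = 1,
                                    seed = 1L) {
  validate_phylogeny(tree)
  if (n_traits < 1L) stop("n_traits must be at least 1")
  n <- ape::Ntip(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  depth <- ape::node.depth.edgelength(tree)
  br <- branch_table(tree)
  m <- nrow(br)

  ie_node <- pidc_node <- true_node <- matrix(NA_real_, tree$Nnode, n_traits)
  ie_br <- pidc_br <- true_br <- matrix(NA_real_, m, n_traits)
  sr <- tc <- matrix(NA_real_, m, n_traits)
  n_undef <- 0L

  for (i in seq_len(n_traits)) {
    tru <- simulate_bm_trait(tree, sigma2 = sigma2, root_value = 0,
                             seed = replicate_seed(seed, i))
    true_node[, i] <- tru$log_values[internal]
    true_br[, i] <- tru$branch$std_change
    tc[, i] <- tru$branch$change

    fit <- ie_reconstruct(tree, tru$tips, metric = "ie", on_undefined = "NA")
    if (fit$n_undefined > 0L) n_undef <- n_undef + 1L
    ie_node[, i] <- fit$node$log_ancestral_state
    ie_br[, i] <- fit$branch$contrast
    sr[, i] <- fit$branch$signed_R

    pd <- pidc_contrasts(tree, tru$log_tips)
    pidc_node[, i] <- unname(pic_ancestral_states(tree, tru$log_tips))
    pidc_br[, i] <- pd$contrast
  }

  nodes <- rbind(
    .bias_summary(internal, depth[internal], ie_node - true_node,
                  ie_node, "IE"),
    .bias_summary(internal, depth[internal], pidc_node - true_node,
                  pidc_node, "PIDC"))
  bdep <- depth[br$child]
  branches <- rbind(
    .bias_summary(br$branch, bdep, ie_br - true_br, ie_br, "IE"),
    .bias_summary(br$branch, bdep, pidc_br - true_br, pidc_br, "PIDC"),
    .bias_summary(br$branch, bdep, true_br - true_br, true_br, "truth"))
  rownames(nodes) <- rownames(branches) <- NULL

  structure(list(nodes = nodes, branches = branches,
                 rvalues = list(signed_R = sr, true_change = tc,
                                branch = br$branch, depth = bdep),
                 raw = list(node = internal, node_depth = depth[internal],
                            ie_node = ie_node, pidc_node = pidc_node,
                            true_node = true_node,
                            branch = br$branch, branch_depth = bdep,
                            ie_branch = ie_br, pidc_branch = pidc_br,
                            true_branch = true_br),
                 n_traits = n_traits, sigma2 = sigma2, seed = seed,
                 n_undefined = n_undef, tree = tree),
            class = "bias_experiment")
}

#' @export
print.bias_experiment <- function(x, ...) {
  cat("Single-trait bias experiment:", x$n_traits, "geometric-BM replicates",
      "on a", ape::Ntip(x$tree), "tip tree (sigma2 =", x$sigma2, ")\n")
  root <- x$nodes[x$nodes$depth == min(x$nodes$depth), ]
  cat("  root-node mean log bias:  IE",
      format(root$mean_bias[root$method == "IE"], digits = 4),
      "  PIDC", format(root$mean_bias[root$method == "PIDC"], digits = 4),
      "\n")
  cat("  replicates with undefined IE states:", x$n_undefined, "\n")
  invisible(x)
}

#' Accuracy of R-values as branch-change estimates
#'
#' @param rvalues the `rvalues` component of a [single_trait_experiment()]
#'   result (or any list with matrices `signed_R` and `true_change`).
#' @return Data frame, one row per branch: Pearson correlation of signed
#'   R-value with true log-space change, mean sign agreement, and mean
#'   (R minus true change), across replicates.
#' @export
rvalue_accuracy <- function(rvalues) {
  sr <- rvalues$signed_R; tc <- rvalues$true_change
  if (ncol(sr) < 10L) stop("need at least 10 replicates")
  m <- nrow(sr)
  cor_b <- sign_b <- bias_b <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    ok <- is.finite(sr[j, ]) & is.finite(tc[j, ])
    if (sum(ok) >= 3L && stats::sd(tc[j, ok]) > 0 &&
        stats::sd(sr[j, ok]) > 0)
      cor_b[j] <- stats::cor(sr[j, ok], tc[j, ok])
    sign_b[j] <- mean(sign(sr[j, ok]) == sign(tc[j, ok]))
    bias_b[j] <- mean(sr[j, ok] - tc[j, ok])
  }
  out <- data.frame(branch = rvalues$branch, depth = rvalues$depth,
                    correlation = cor_b, sign_agreement = sign_b,
                    mean_bias = bias_b)
  out[order(out$depth, out$branch), , drop = FALSE]
}

#' Paired-trait slope-recovery experiment
#'
#' Sweeps the evolutionary regression coefficient evenly from 0 to 1 over
#' `n_pairs` correlated-BM trait pairs on `tree`. For each pair the slope of
#' trait 2's change on trait 1's change is estimated four ways, always by
#' OLS through the origin: PIC (`n - 1` independent contrasts of the logged
#' traits), PIDC (`2n - 2` directional contrasts), IE standardized
#' directional contrasts, and IE signed R-values (IE fitted to the
#' exponentiated traits). A meta-slope per method — origin-OLS of estimated
#' on simulated coefficients — summarises recovery: 1 means unbiased.
#'
#' Pairs in which IE produces undefined values are dropped from the IE
#' meta-regressions only (their count is reported); PIC and PIDC keep all
#' pairs.
#'
#' @param tree a validated `"phylo"` object.
#' @param n_pairs number of trait pairs (>= 2).
#' @param seed master seed.
#' @return An object of class `"slope_recovery"`: list with `pairs` (data
#'   frame: `beta`, `pic`, `pidc`, `ie`, `ie_r`), `meta` (named vector of
#'   meta-slopes), and `n_dropped` (named vector, pairs excluded per IE
#'   method).
#' @export
pair_trait_experiment <- function(tree, n_pairs = 500, seed = 1L) {
  validate_phylogeny(tree)
  betas <- beta_grid(n_pairs)
  res <- data.frame(beta = betas, pic = NA_real_, pidc = NA_real_,
                    ie = NA_real_, ie_r = NA_real_)
  for (i in seq_len(n_pairs)) {
    pr <- simulate_correlated_pair(tree, betas[i],
                                   seed = replicate_seed(seed, i))
    l1 <- pr$trait1$log_tips; l2 <- pr$trait2$log_tips
    res$pic[i] <- origin_ols(pic_contrasts(tree, l1)$contrast,
                             pic_contrasts(tree, l2)$contrast)
    res$pidc[i] <- origin_ols(pidc_contrasts(tree, l1)$contrast,
                              pidc_contrasts(tree, l2)$contrast)
    f1 <- ie_reconstruct(tree, pr$trait1$tips, metric = "ie",
                         on_undefined = "NA")
    f2 <- ie_reconstruct(tree, pr$trait2$tips, metric = "ie",
                         on_undefined = "NA")
    ok_c <- is.finite(f1$branch$contrast) & is.finite(f2$branch$contrast)
    if (sum(ok_c) >= 2L && any(f1$branch$contrast[ok_c] != 0))
      res$ie[i] <- origin_ols(f1$branch$contrast[ok_c],
                              f2$branch$contrast[ok_c])
    ok_r <- is.finite(f1$branch$signed_R) & is.finite(f2$branch$signed_R)
    if (sum(ok_r) >= 2L && any(f1$branch$signed_R[ok_r] != 0))
      res$ie_r[i] <- origin_ols(f1$branch$signed_R[ok_r],
                                f2$branch$signed_R[ok_r])
  }
  meta <- c(pic = origin_ols(res$beta, res$pic),
            pidc = origin_ols(res$beta, res$pidc),
            ie = origin_ols(res$beta, res$ie),
            ie_r = origin_ols(res$beta, res$ie_r))
  structure(list(pairs = res, meta = meta,
                 n_dropped = c(ie = sum(!is.finite(res$ie)),
                               ie_r = sum(!is.finite(res$ie_r))),
                 n_pairs = n_pairs, seed = seed, tree = tree),
            class = "slope_recovery")
}

#' @export
print.slope_recovery <- function(x, ...) {
  cat("Slope recovery over", x$n_pairs, "correlated-BM trait pairs",
      "(beta swept 0 to 1) on a", ape::Ntip(x$tree), "tip tree\n")
  cat("  meta-slopes (origin OLS of estimated on simulated):\n")
  print(round(x$meta, 3))
  if (any(x$n_dropped > 0))
    cat("  pairs dropped from IE meta-regressions:",
        paste(names(x$n_dropped), x$n_dropped, collapse = ", "), "\n")
  invisible(x)
}
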