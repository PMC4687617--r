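test_that("the IE metric is proportional, bounded, and fails at zero sums", {
  expect_equal(ie_distance(5, 5), 0)
  expect_equal(ie_distance(1, 3), 1)
  expect_equal(ie_distance(3, 1), 1)          # symmetric
  expect_lt(2 - ie_distance(1, 1e9), 1e-6)    # asymptote at 2
  expect_lt(ie_distance(1, 1e15), 2)
  expect_error(ie_distance(1, -1), "x \\+ y = 0")
})

test_that("the log-difference metric is the unbiased proportional distance", {
  expect_equal(log_distance(exp(1), 1), 1)
  expect_equal(log_distance(5, 5), 0)
  expect_equal(log_distance(1, 3), log(3))
  expect_equal(log_distance(3, 1), log(3))
  expect_error(log_distance(-1, 2), "positive")
  expect_error(log_distance(2, 0), "positive")
})

test_that("adaptive peak is the inverse-path-distance weighted tip mean", {
  tr <- read_tree(text = "(A:1,B:1);")
  expect_equal(adaptive_peak(tr, c(A = 2, B = 8), 3), 5)
  tr2 <- read_tree(text = "(A:1,B:3);")
  expect_equal(adaptive_peak(tr2, c(A = 2, B = 8), 3),
               (2 / 1 + 8 / 3) / (1 + 1 / 3))  # 3.5
  # constant tips give the constant, on any tree
  tt <- simulate_tree(30, seed = 11)
  x <- setNames(rep(7, 30), tt$tip.label)
  for (v in c(31L, 45L, 59L))
    expect_equal(adaptive_peak(tt, x, v), 7)
  # and the peak always lies within the tip range
  tru <- simulate_bm_trait(tt, seed = 12)
  aps <- vapply(31:59, function(v) adaptive_peak(tt, tru$tips, v), 0)
  expect_true(all(aps >= min(tru$tips) & aps <= max(tru$tips)))
  expect_error(adaptive_peak(tt, tru$tips, 1L), "internal")
})

test_that("Farris T-distances follow the (two sides minus third)/2 rule", {
  tt <- farris_T(1.2, 0.24, 1.04)
  expect_equal(tt$T1, 1.0)
  expect_equal(tt$T2, 0.2)
  expect_equal(tt$T3, 0.04)
  # collinear sides: peak-to-ancestor distance collapses to zero
  cl <- farris_T(0.7, 0.3, 0.4)
  expect_equal(cl$T3, 0)
  # equilateral symmetry
  eq <- farris_T(0.6, 0.6, 0.6)
  expect_equal(unlist(eq), c(T1 = 0.3, T2 = 0.3, T3 = 0.3))
})

test_that("R-values scale T by relative branch length", {
  expect_equal(r_values(0.5, 0.3, 2, 2), list(R1 = 0.5, R2 = 0.3))
  expect_equal(r_values(1, 1, 3, 1), list(R1 = 1.5, R2 = 0.5))
  expect_equal(r_values(0, 0.4, 1, 5)$R1, 0)
  expect_error(r_values(1, 1, 0, 1), "positive")
})

test_that("ancestral state is the inverse-R weighted mean of the sisters", {
  expect_equal(ancestral_state(2, 8, 0.5, 0.5), 5)
  expect_equal(ancestral_state(2, 8, 1, 3), (2 / 1 + 8 / 3) / (1 + 1 / 3))
  expect_error(ancestral_state(4, 4, 0, 0.3), "undefined")
})

test_that("ie_reconstruct emits n-1 states and 2n-2 branch values", {
  tt <- simulate_tree(100, seed = 1)
  tru <- simulate_bm_trait(tt, seed = 2)
  fit <- ie_reconstruct(tt, tru$tips)
  expect_s3_class(fit, "ie_fit")
  expect_equal(nrow(fit$node), 99L)
  expect_equal(nrow(fit$branch), 198L)
  expect_true(all(is.finite(fit$node$ancestral_state)))
  # positive-value domain: all sides < 2, all unsigned R >= 0
  expect_true(all(fit$branch[, c("S1", "S2", "S3")] < 2))
  expect_true(all(fit$branch$R >= 0))
  expect_true(all(abs(fit$branch$signed_R) == fit$branch$R))
  # ancestral states stay within the tip range (weighted means of tips)
  expect_true(all(fit$node$ancestral_state >= min(tru$tips) &
                    fit$node$ancestral_state <= max(tru$tips)))
  # contrasts are the standardized log differences along each branch
  logv <- c(unname(log(tru$tips[tt$tip.label])), fit$node$log_ancestral_state)
  expect_equal(fit$branch$contrast,
               (logv[fit$branch$child] - logv[fit$branch$parent]) /
                 sqrt(fit$branch$length),
               tolerance = 1e-12)
})

test_that("degenerate inputs raise descriptive errors or NaN as requested", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  expect_error(ie_reconstruct(tr, c(A = 4, B = 4, C = 4)), "node")
  expect_error(ie_reconstruct(tr, c(A = -1, B = 2, C = 3)), "positive")
  f <- ie_reconstruct(tr, c(A = 4, B = 4, C = 4), on_undefined = "NA")
  expect_gt(f$n_undefined, 0L)
  expect_true(any(is.nan(f$node$ancestral_state)))
})

test_that("modified IE on an equal-branch cherry returns the adaptive peak", {
  set.seed(99)
  for (i in 1:1000) {
    b <- runif(1, 0.1, 5)
    x <- exp(rnorm(2, 0, 2))
    while (x[1] == x[2]) x <- exp(rnorm(2, 0, 2))
    tr <- read_tree(text = sprintf("(A:%g,B:%g);", b, b))
    fit <- ie_reconstruct(tr, c(A = x[1], B = x[2]), metric = "log")
    expect_equal(fit$node$ancestral_state, fit$node$adaptive_peak,
                 tolerance = 1e-10)
  }
})

test_that("log-difference metric on a cherry gives T3 = 0 exactly", {
  tr <- read_tree(text = "(A:1,B:1);")
  fit <- ie_reconstruct(tr, c(A = 2, B = 8), metric = "log")
  # the peak vertex is collinear with the two tips in log space
  s <- fit$branch[1, ]
  T3 <- (s$S2 + s$S3 - s$S1) / 2
  expect_equal(T3, 0)
})

test_that("IE inflates the root state of geometric BM data", {
  tt <- simulate_tree(100, seed = 1)
  rkids <- tt$edge[tt$edge[, 1] == 101L, 2L]
  nrep <- 200
  root_log <- numeric(nrep)
  root_contr <- matrix(NA_real_, 2, nrep)
  for (i in seq_len(nrep)) {
    tru <- simulate_bm_trait(tt, sigma2 = 1, root_value = 0,
                             seed = replicate_seed(60, i))
    fit <- ie_reconstruct(tt, tru$tips, on_undefined = "NA")
    root_log[i] <- fit$node$log_ancestral_state[fit$node$depth == 0]
    root_contr[, i] <- fit$branch$contrast[fit$branch$child %in% rkids]
  }
  # root estimate biased toward positive log values ...
  expect_lt(t.test(root_log, alternative = "greater")$p.value, 0.01)
  # ... and root-adjacent standardized contrasts skewed negative
  expect_lt(t.test(c(root_contr), alternative = "less")$p.value, 0.01)
})
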