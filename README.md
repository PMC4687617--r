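# ieaudit

Tools for auditing the **Independent Evolution (IE)** phylogenetic
comparative method.

IE is an algorithm that promises, from a resolved phylogeny with branch
lengths and one continuous trait value per tip, (i) an ancestral state at
every internal node and (ii) a separate "rate of evolutionary change"
(an *R*-value) for every branch. It has been used to study brain–body
allometry, mosaic brain evolution and macroevolutionary rate hypotheses,
yet it is not grounded in an explicit statistical model. This package
re-implements the algorithm exactly as published so that its statistical
behaviour can be examined, and pairs it with everything needed for that
audit:

* **`ie_reconstruct()`** — the eight-step IE algorithm. Adaptive peaks
  `AP = Σ(x_i/d_i) / Σ(1/d_i)` (inverse path-distance weighted means of
  all tips) are precomputed for every internal node; the tree is then
  collapsed cherry by cherry, treating the two descendant values and the
  parent's adaptive peak as triangle vertices with side lengths from the
  proportional metric `S = 2|x−y|/(x+y)`, converting sides to vertex
  distances with the Farris formulas `T = (two incident sides − opposite
  side)/2`, scaling `R_i = T_i · 2b_i/(b_1+b_2)`, and reconstructing the
  ancestor as the inverse-*R* weighted mean of the two descendants. A
  `metric = "log"` variant substitutes log-transformed data and
  log-difference side lengths (under which the "adaptive peak" provably
  coincides with the ancestral state for equal-branch cherries).
* **`apollonius_centroid_distances()`** — the *correct* vertex-to-centroid
  geometry, `T_A = √(2b² + 2c² − a²)/3`, showing the Farris formulas are
  not centroid distances.
* **`pic_contrasts()`, `pic_ancestral_states()`, `pidc_contrasts()`** —
  the reference methods: phylogenetically independent contrasts and
  partially independent directional contrasts
  (`(child − parent)/√branch length` with pruning-pass ancestors).
* **`simulate_tree()`, `simulate_bm_trait()`, `simulate_correlated_pair()`**
  — geometric Brownian-motion simulation with exact per-node and
  per-branch ground truth, including correlated pairs with a chosen
  evolutionary regression coefficient β.
* **`single_trait_experiment()`, `pair_trait_experiment()`,
  `rvalue_accuracy()`** — the two audit experiments: per-node/per-branch
  bias of IE vs PIDC, and recovery of β by PIC, PIDC, IE contrasts and IE
  *R*-values (origin-OLS meta-regression of estimated on simulated
  slopes).

## Worked example

The three-taxon tree from the method's original illustration:

```r
library(ieaudit)
tr  <- read_tree(text = "((A:8,B:8):3,C:11);")
fit <- ie_reconstruct(tr, c(A = 2, B = 8, C = 5))
fit
#> Independent Evolution reconstruction (metric: IE proportional)
#>   3 tips; 2 ancestral states; 4 branch R-values
#>   root state: 5 (adaptive peak 5)
round(fit$branch[, c("parent","child","length","T","R","signed_R","contrast")], 4)
#>   parent child length      T      R signed_R contrast
#> 1      4     5      3 0.1800 0.0771   0.0771   0.1042
#> 2      5     1      8 0.7978 0.7978  -0.7978  -0.3878
#> 3      5     2      8 0.4022 0.4022   0.4022   0.1024
#> 4      4     3     11 0.0000 0.0000   0.0000   0.0000
```

Branch 5→1 (tip A) receives a large *R*-value, signed negative because A
(value 2) sits below its reconstructed ancestor (5.99); the root's branch
to C gets `R = 0` because C's value equals the root's adaptive peak — one
of the degenerate geometries the audit documents.

The bias experiment on a 100-tip surrogate tree shows the method's
systematic ancestral-state inflation (true root log value is 0):

```r
tree <- simulate_tree(100, seed = 1)
ex   <- single_trait_experiment(tree, n_traits = 200, seed = 1)
ex
#> Single-trait bias experiment: 200 geometric-BM replicates on a 100 tip tree (sigma2 = 1 )
#>   root-node mean log bias:  IE 0.3786   PIDC -0.00507
#>   replicates with undefined IE states: 0
```

IE overestimates the root's log value by ~0.38 (a ~46% overestimate on
the arithmetic scale) while the directional-contrast reference method is
unbiased to Monte-Carlo precision.

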