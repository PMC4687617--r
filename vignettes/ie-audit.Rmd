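---
title: "Auditing the Independent Evolution method: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the Independent Evolution method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieaudit)
```

## What is being audited, and why

Independent Evolution (IE) is an algorithm that takes a fully resolved
rooted phylogeny with branch lengths and one positive continuous trait
value per tip, and returns an ancestral state for each of the $n-1$
internal nodes plus a branch-specific "rate of change" (an $R$-value) for
each of the $2n-2$ branches. Unlike Brownian-motion (BM) or
Ornstein–Uhlenbeck based comparative methods it is not derived from an
explicit stochastic model, so its sampling behaviour can only be
established empirically. This package implements the algorithm exactly as
published, together with reference methods and simulators, so that three
questions can be answered with tested code:

1. Are IE ancestral states and branch changes unbiased when data evolve
   under the simplest standard model (geometric BM)?
2. Do $R$-values track the true change on individual branches?
3. When branch changes of two traits are regressed on one another, does
   the slope recover the simulated evolutionary regression coefficient?

## The IE algorithm as implemented

Given tip values $x_1,\dots,x_n > 0$:

1. **Adaptive peaks.** For every internal node $v$,
   $AP_v = \sum_i (x_i/d_i) \big/ \sum_i (1/d_i)$, where $d_i$ is the
   branch-path distance from tip $i$ to $v$ and the sum runs over *all*
   tips. The published phrasing ("weighted by their distances … divided by
   the sum of the inverse distances") is internally inconsistent; the
   inverse-distance reading is the only one that extends Felsenstein's
   two-tip ancestor formula (which the method cites as its basis) and
   reproduces the algebra of the method's own appendix, so it is the one
   implemented. Peaks are computed once, from the original tips, and never
   updated during the traversal.
2. **Cherry collapse.** The tree is traversed from the tips: repeatedly
   take a cherry (an internal node both of whose children carry values),
   treat the two child values $x_1, x_2$ and the parent's $AP$ as triangle
   vertices, and measure side lengths with the proportional metric
   $S = 2|x-y|/(x+y)$ ($S_1$ between the children, $S_2$ from child 2 to
   the peak, $S_3$ from child 1 to the peak).
3. **Farris distances.** $T_1 = (S_1+S_3-S_2)/2$,
   $T_2 = (S_1+S_2-S_3)/2$, $T_3 = (S_2+S_3-S_1)/2$. These are Wagner-tree
   formulas, not centroid geometry; the correct centroid distances are
   $\sqrt{2b^2+2c^2-a^2}/3$ (vertex opposite side $a$), provided as
   `apollonius_centroid_distances()` for comparison. On the worked
   triangle with sides $(1.2, 0.24, 1.04)$ the two disagree sharply
   (`farris_T()` gives $1.0, 0.2, 0.04$; the true distances are
   $0.74, 0.46, 0.31$).
4. **R-values and the ancestor.** $R_i = T_i \cdot 2b_i/(b_1+b_2)$ (the
   published scaling, implemented verbatim — no rationale for it is given
   in the source material), and the ancestral state is the
   inverse-$R$ weighted mean $A = (x_1/R_1 + x_2/R_2)/(1/R_1 + 1/R_2)$.
   $A$ replaces the cherry; the parent keeps its own original branch
   length, matching the method's published three-taxon illustration.
5. **Outputs.** After reaching the root, each branch's $R$ is signed by
   the direction of reconstructed change along it, and a log-space
   standardized directional contrast
   $(\ln x_\text{child} - \ln x_\text{parent})/\sqrt{b}$ is attached to
   every branch so IE can be compared on the same scale as the reference
   methods.

The **modified variant** (`metric = "log"`) log-transforms the data before
step 1 and uses plain differences of logged values as side lengths. For an
equal-branch cherry whose peak lies between the two values this makes
$T_3 = 0$ and $A = AP$ exactly — the package's tests verify this
equivalence to $10^{-10}$ relative tolerance over 1,000 random cherries —
showing the "adaptive peak" of the original method is an artefact of the
untransformed scale and the bounded metric.

### Degenerate inputs

The metric is undefined when two vertices sum to zero (impossible for the
positive data the method requires; negative inputs are rejected up
front) and the ancestor is undefined whenever an $R$-value is zero, i.e.
whenever two triangle vertices coincide. By default these raise errors
naming the node; `on_undefined = "NA"` records `NaN` and continues
(NaN propagates rootward and is counted), which the bulk experiments use
so that rare degenerate draws cannot abort a simulation. A subtler
numerical point: when the peak falls *outside* the cherry interval, the
relevant $T$ is second order in the side lengths (the metric's strict
concavity is all that keeps it positive), so as trait variation shrinks
toward zero the triangle becomes numerically collinear and the state
undefined — the package's tests therefore probe the small-variance limit
at $\sigma^2 = 10^{-6}$–$10^{-10}$, not at machine-zero variance.

## Reference methods

* `pic_ancestral_states()` returns the *local* pruning-pass estimates (at
  each node, the inverse-adjusted-branch-length weighted mean of its two
  daughters, with the standard $b' = b + b_Lb_R/(b_L+b_R)$ adjustment),
  via `ape::ace(method = "pic")`; an independently coded pruning pass in
  the test suite confirms the equivalence. Global (re-rooted) ML estimates
  are deliberately not used: the directional-contrast comparator is
  defined on the local estimates.
* `pic_contrasts()` gives the $n-1$ standardized independent contrasts
  (`ape::pic`).
* `pidc_contrasts()` gives the $2n-2$ partially independent directional
  contrasts $(x_\text{child} - \hat x_\text{parent})/\sqrt{b}$ — the
  natural "fair comparison" for IE, since it makes the same kind of
  per-branch claim but from a model-based ancestor.

PIC/PIDC consume log-transformed data (BM requires mean–variance
independence); IE consumes the untransformed arithmetic values, as its
authors prescribe; IE ancestral states are log-transformed afterwards so
every comparison happens in log space.

## The simulator and what it emulates

`simulate_bm_trait()` draws each branch's change independently from
$\mathcal N(0, \sigma^2 b)$ in log space, accumulates along the tree, and
exponentiates — geometric BM, the generating model of the audit. The
per-branch construction (rather than one multivariate-normal tip draw) is
distributionally identical under BM and records the exact truth for every
node and branch, which per-branch comparisons need.
`simulate_correlated_pair()` uses per-branch bivariate increments with
unit marginal rates and covariance $\beta$, so $\beta$ *is* the
evolutionary regression coefficient of trait 2 on trait 1;
`beta_grid()` sweeps it linearly over $[0,1]$ ("incremented from 0 to 1"
admits many spacings; linear is the simplest faithful reading).

Defaults follow the study conditions: $\sigma^2 = 1$, root log value 0,
1000 single-trait replicates, 500 trait pairs. Surrogate trees are
pure-birth (`ape::rphylo`) with 100 tips, rescaled to unit root-to-tip
height so that a unit rate yields unit log-variance at the tips — a
standard normalization that fixes the signal scale independently of the
birth-rate parameterization. One master seed spawns per-replicate seeds by
fixed arithmetic (`replicate_seed()`), so any single replicate is
reproducible in isolation.

What the surrogate trees do **not** emulate: the consensus primate
phylogeny used in the original study. Quantities tied to that specific
tree — the published IE meta-slopes of 0.78 and 0.81, its branch
numbering, its particular depth profile — are not reproduced here; on
random trees only the qualitative findings (inflation near the root,
negative skew of root-ward contrasts, attenuated and crossing slope
recovery, erratic $R$-values) are stable, and those are what the tests
assert. A user holding the original NEXUS tree can pass it through
`read_tree()` and rerun both experiments unchanged.

## The experiments

`single_trait_experiment()` runs IE and PIDC over replicate traits and
summarises estimate-minus-truth per node and per branch (ordered by
distance from the root), keeping the raw replicate matrices for
significance tests and the per-branch (signed $R$, true change) pairs for
`rvalue_accuracy()`. `pair_trait_experiment()` estimates each pair's slope
by OLS through the origin (`origin_ols()`, $\hat\beta = \sum xy/\sum x^2$
— contrasts have no intercept) for PIC, PIDC, IE contrasts and signed IE
$R$-values, then meta-regresses estimated on simulated slopes. Pairs with
undefined IE values are dropped from the IE meta-regressions only, with
counts reported; PIC/PIDC keep every pair. Signed (not unsigned)
$R$-values enter the regressions, since unsigned ones cannot carry
direction.

## Conventions and numerical choices

* **Node/branch identity.** Standard `"phylo"` numbering (tips
  $1..n$, root $n+1$); a branch is identified by its child node. This is
  deterministic for a given Newick string and is what every downstream
  `ape` consumer expects, so it is used instead of inventing a separate
  postorder labelling.
* **Traversal order.** When several cherries coexist, the deepest
  (greatest root distance) is processed first, ties broken by node
  number. Results are order-independent — each cherry's inputs are fixed
  before collapse — but the fixed order makes error reports reproducible.
* **Tolerances.** Geometry oracles are checked to $10^{-10}$ relative;
  stochastic properties use Monte-Carlo error bands derived from the
  replicate count. Per-branch standardized contrasts on very short
  branches divide node-estimate noise by $\sqrt b$, so their replicate
  means are judged by $t$-statistic rather than a fixed band — a fixed
  $\pm 0.05$ band is only resolvable where the standard error is well
  below it.
* **Problem sizes.** The shipped tests and the acceptance script use
  100-tip trees, 1000 single-trait replicates and 500 pairs — the study
  scale, which runs in seconds here.

## Known limitations

* No Ornstein–Uhlenbeck or rate-shift simulation or fitting; the audit's
  generating model is plain BM by design.
* Negative or zero trait values are rejected, not supported: they are a
  documented failure mode of the IE metric, not a feature to emulate.
* No "repair" of IE beyond the published modified variant is attempted;
  the modified variant exists to expose the adaptive peak's collapse, not
  as a recommended method.
* `pic_ancestral_states()` is the local pruning estimator only; users
  wanting re-rooted ML states should call `ape::ace` directly.
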