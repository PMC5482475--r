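---
title: "Estimation assumptions and the networks they produce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimation assumptions and the networks they produce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingbet)
```

## The model

`isingbet` works with the Ising model over $P$ binary variables coded
$\{0, 1\}$:

$$\Pr(X = x) \propto \exp\Big(\sum_i \tau_i x_i +
  \sum_{i<j} \omega_{ij} x_i x_j\Big),$$

with node thresholds $\tau$ (log-odds units) and a symmetric,
zero-diagonal weight matrix $\omega$ carrying $P(P-1)/2$ pairwise
interactions. An absent edge ($\omega_{ij} = 0$) means conditional
independence of nodes $i$ and $j$ given the rest. The $\{0,1\}$ coding is
deliberate and matters: it is the coding under which nodewise logistic
regression and the eLasso operate, and the same dependence structure has
different parameter values under $\pm 1$ coding.

With $P(P-1)/2 + P$ free parameters and the sample sizes typical of
symptom questionnaires, unconstrained estimation is noisy, so every
practical estimator constrains the parameter space somehow — and the
constraint it assumes is visible in the network it returns. The package
exists to make that circularity measurable: it provides generators whose
ground truth is known (dense, sparse, or latent-variable) and five
estimators whose assumptions differ, plus metrics that score each
estimate against the truth.

## Generators

**Curie-Weiss** (`make_curie_weiss`): every pair gets the same weight
$w$ (default 0.2, the value used throughout the simulation designs),
every node the same threshold (default 0 — the generating thresholds are
not dictated by the designs, and 0 puts all marginals near one half,
the least degenerate choice). The weight matrix is rank 1 up to its
diagonal: a dense truth.

**Random sparse** (`make_random_sparse`): `round(density * P(P-1)/2)`
pairs chosen uniformly by seed get weight $w$; defaults density 0.2,
$w = 0.2$. A sparse truth.

**Comorbidity MIRT** (`build_comorbidity_mirt`): a 19-item, 8-latent
2PL model of two comorbid disorders — dysthymia (D1–D10) and generalized
anxiety (G1–G9). Every item loads 1 on its own disorder trait
(interchangeable symptoms), all difficulties are 0, the traits correlate
0.55, and all latents have SD 1. Two orthogonal contrast factors load
$\pm 1.1$ on the mutually exclusive pairs (D2, D3) and (G6, G7); four
orthogonal bridge factors load 0.75 on each shared symptom pair
(D7, G6), (D8, G7), (D9, G8), (D10, G9). No skip structure is imposed.
The Ising network this model induces is dense and clustered, with
negative edges inside the exclusive pairs and positive bridges between
the shared pairs — a truth that is neither sparse nor exactly low rank.

The logistic link is used without the 1.7 scaling constant, because the
Ising/latent-trait correspondence below is a statement about logistic
models.

What the generators emulate is the *structure* of psychopathology data:
binary symptom indicators whose co-occurrence is driven by dense
pairwise interactions or by latent traits. What they do not emulate:
item missingness, skip structures, acquiescence or other response
styles, ordinal severity scales, and sampling designs other than i.i.d.
rows. Passing tests therefore demonstrate properties of the estimators
under clean i.i.d. binary data, not robustness to the measurement
artifacts of real questionnaires.

## Sampling

`pattern_distribution` enumerates all $2^P$ patterns (capped at
$P \le 20$; patterns are indexed with node 1 as the least significant
bit). `sample_ising` draws i.i.d. patterns by inverse-CDF lookup on that
enumeration, or by Gibbs sampling — one independent chain per
observation, updated in lock-step, 200 burn-in sweeps by default, so
rows are independent by construction. The two samplers are tested
against each other and against enumeration on all first and second
moments.

## The Rasch equivalence

A Curie-Weiss model with weight $w \ge 0$ and threshold $\tau$ is
exactly a marginal unidimensional Rasch model. Writing
$s = \sum_i x_i$, the pairwise energy is $(w/2)(s^2 - s)$, and the
Gaussian identity $\int N(t; 0, w)e^{ts}dt = e^{ws^2/2}$ replaces the
quadratic by a latent variable $t$ with variance $w$ and common item
easiness $b = \tau - w/2$. Carrying the normalization through, the
latent density under which the pattern distributions agree *exactly* is
not $N(0, w)$ but the tilted density

$$g(t) \propto (1 + e^{b+t})^P \, N(t; 0, w).$$

`rasch_pattern_distribution` integrates against $g$ with Gauss–Hermite
quadrature (61 nodes by default; 61 is far past the point where the
quadrature error is at machine precision for $w \le 0.5$) and reproduces
the enumerated Curie-Weiss distribution to total-variation distance
below $10^{-12}$ across $w \in \{0.05, 0.2, 0.5\}$,
$\tau \in \{-1, 0, 1\}$, $P \in \{3, 8\}$. Integrating against the
plain normal instead gives a genuinely different distribution (TV up to
0.9 on the same grid) — that is the marginal-versus-posterior
distinction between the two model families, and the package implements
the exact mixture direction.

## Estimators

All five estimators return an `ising_fit`: an `ising_model` plus method
metadata. All of them guarantee an exactly symmetric, zero-diagonal
weight matrix.

* **`fit_nodewise`** — per-node maximum-likelihood logistic regression;
  directed coefficients combined by the unconditional mean
  (`symmetrize(, "average")`), since ML coefficients are never exactly
  zero. Requires $n \ge P$ and no constant columns; a coefficient
  beyond 30 on the logit scale is treated as separation and reported as
  an error naming the node.
* **`fit_elasso`** — the sparsity bet. Per node an L1 path of 100
  log-spaced penalties from $\lambda_{\max} = \max_j |x_j'(y - \bar y)|/n$
  down to $0.01\,\lambda_{\max}$ (predictors are left on their common
  0/1 scale rather than standardized), selected by EBIC
  $-2\ell + k\ln n + 2\gamma k \ln(P-1)$ with $k$ counting active edge
  coefficients only and $\gamma = 0.25$; ties go to the larger penalty.
  The AND-rule (mean if both directed coefficients are nonzero, else 0)
  symmetrizes. $\gamma = 0$ gives plain BIC selection.
* **`fit_loglinear`** — the full-information unregularized fit:
  cross-classify into the $2^P$ table (capped at $P \le 15$) and fit a
  Poisson log-linear model with all main effects and two-way
  interactions under 0/1 dummy coding; interactions are the weights,
  main effects the thresholds. Zero margins make the MLE infinite; this
  is reported as an error unless an explicit smoothing constant is
  supplied. On a saturated $2\times 2$ table the edge weight is the log
  odds ratio, which pins the implementation to a closed form.
* **`fit_low_rank`** — the density bet. Maximizes the joint
  pseudolikelihood over thresholds and a symmetric weight matrix of
  rank at most $k$, by projected gradient ascent: after each ascent
  step the matrix is projected by truncated eigendecomposition
  (largest-magnitude eigenvalues), and the diagonal the projection
  induces is absorbed into the thresholds, exactly valid on 0/1 data
  where $x^2 = x$. A backtracking line search keeps the objective
  monotone. The optimizer state keeps the rank-$k$ matrix *with* its
  diagonal; projecting the zero-diagonal weight matrix instead would
  make arbitrarily small steps leave the feasible point and stall the
  line search. The rank constraint makes the problem non-convex, so the
  fit runs three starts — a pairwise log-odds-ratio initialization
  (whose sign pattern places the search in the right basin), a random
  near-zero start, and a perturbed data-driven start — and returns the
  best by pseudolikelihood. With $k = P$ the projection is vacuous and
  the concave unconstrained optimum is recovered, which is the
  correctness oracle used in the tests. Convergence is declared at
  relative objective change below `tol` (default $10^{-8}$);
  non-convergence is flagged on the result, not thrown.
* **`fit_elasticnet_cv`** — per node a grid over the mixing parameter
  $\alpha \in \{0, 0.1, \ldots, 1\}$ and the penalty, tuned by 10-fold
  cross-validated logistic deviance with a seed-fixed fold assignment
  shared across nodes; coefficients at the selected pair are
  AND-symmetrized on exact zeros. When cross-validation prefers
  $\alpha$ near 0 (ridge), nothing is exactly zero and the selected
  network is dense — which is what happens on latent-variable data.

Numerical choices worth stating: the eLasso penalty grid is pinned at
100 points with ratio 0.01 (common practice; the designs do not dictate
it); the EBIC tie-break prefers the sparser model for determinism; edge
presence everywhere uses the zero tolerance $10^{-8}$, which separates
the structural zeros of L1 selection from the numerically small weights
of dense estimators; the unregularized symmetrization default is the
plain average, as the AND/OR distinction is vacuous without exact
zeros.

## Recovery metrics and the study pipeline

`recovery_metrics` compares strict upper triangles at a zero tolerance:
confusion counts, sensitivity, specificity, mean absolute weight error,
weight correlation and density. Undefined quantities (no true edges, no
true non-edges, zero-variance weights) are flagged `NA`, never coerced
to 0, and serialize as empty CSV cells. Edge detection uses $|\omega|$:
a negative edge is an edge.

`run_study` orchestrates the three designs. Per replication one dataset
of `max(n_grid)` rows is drawn and every method fits its first-$n$
prefixes, so smaller samples are nested within larger ones. For the
comorbidity design the reference is a *proxy truth*: an unregularized
fit on `proxy_n` draws from the generator — `fit_loglinear` when
$P \le 15$, otherwise `fit_nodewise`, since the $2^{19}$-cell table is
out of reach; the proxy sharpens as `proxy_n` grows, and the default
200,000 keeps its Monte-Carlo error well below the structural effects
(bridge and exclusivity weights near $\pm 0.45$) while staying
desk-machine sized. Every random component draws its seed from
`seed_stream(seed, label)`, a deterministic 32-bit hash, so any single
replication can be reproduced without replaying the study, and two runs
of the same config are byte-identical down to the serialized CSV and
edge lists.

Default scales — $P = 10$ for the dense and sparse designs, sample grid
$\{100, 250, 500, 1000\}$, 20 replications — are the package's own
choices for a desk-machine study; the designs fix the edge weight
(0.2), sparse density (20%), and the full comorbidity model, but not
the node count or the exact sample-size grid, which stay configurable.

## What the studies show

Run from `analysis/`:

1. **Dense truth** (`01_dense_truth.R`): under a Curie-Weiss truth the
   unregularized fit scatters widely (spurious negative edges), eLasso
   returns a sparse network although no true zero exists, and the
   rank-2 fit tracks the uniform weights best.
2. **Sparse truth** (`02_sparse_truth.R`): with a 20%-density truth the
   roles flip — eLasso keeps specificity near 1 while unregularized and
   rank-2 fits are dense and therefore maximally unspecific.
3. **Comorbidity truth** (`03_mirt_truth.R`): the proxy-truth network is
   dense and clustered with negative exclusivity edges and positive
   bridges; at $n = 1000$ eLasso recovers a much sparser caricature and
   the rank-2 fit recovers the clusters but not the deviations.

None of these numbers is asserted from memory: the figures quoted in
the README are printed by the scripts, and the same quantities are
recomputed by the test suite and `scripts/acceptance.R`.

## Limitations

* Exact enumeration, and hence the exact sampler and the log-linear
  fit, are capped at $P \le 20$ and $P \le 15$ respectively; beyond
  that only Gibbs sampling and nodewise methods apply.
* The low-rank fit maximizes a pseudolikelihood under a non-convex
  constraint; restarts make the returned optimum reliable in the sizes
  tested, but global optimality is not guaranteed, and at small $n$ the
  rank-2 optimum itself can be noisy (its extra eigencomponent can
  absorb sampling noise).
* The MIRT study's reference network is a finite-sample proxy, not the
  analytic Ising counterpart of the generator; metrics against it
  inherit its (small) Monte-Carlo error.
* Cross-validation folds, not information criteria, tune the
  elastic-net; fold-count and loss are pinned choices (10-fold
  deviance), and other choices would select differently near the
  ridge/LASSO boundary.
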