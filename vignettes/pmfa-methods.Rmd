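---
title: "Principal metabolic flux mode analysis: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal metabolic flux mode analysis: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfa)
```

## The problem

PCA on a samples × reactions matrix finds directions of maximal variance,
but its loadings ignore the stoichiometry of the metabolic network: a
principal component is generally not a flux mode, violates reaction
directionality, and is dense. Purely stoichiometric tools (FBA,
elementary-mode analysis) respect the network but analyze one flux
distribution at a time and presume an exact steady state, which real
multi-condition data — transients, perturbations, measurement noise —
rarely satisfies.

PMFA interpolates between the two. With `Σ` the empirical covariance of
column-centered data and `S` the exchange stoichiometric matrix (internal
metabolites × reactions; external species cannot be balanced and are
dropped at load time), one flux mode solves

$$\max_{w}\; w^\top \Sigma w \;-\; \lambda\,\|S w\|,\qquad
  \text{s.t. } w_{ir}\ge 0,\ \|w\|_p = C,$$

where the stoichiometric penalty is either $\|Sw\|_2^2$ (`stoich_norm = 2`)
or $\|Sw\|_1$ (`stoich_norm = 1`), and the loadings live on the $\ell_2$
sphere (`loading_norm = 2`, dense PMFA, $C$ fixed to 1) or the $\ell_1$
sphere (`loading_norm = 1`, sparse SPMFA, budget `C`). The directionality
constraint applies to thermodynamically irreversible reactions and can be
switched off (`directionality = FALSE`), which reintroduces a global sign
indeterminacy; we then flip signs so the largest-magnitude entry is
positive.

Interpretation of the pieces:

* $\lambda$ (dimensionless, default 1) trades explained variance against
  steady-state deviation. $\lambda = 0$ recovers (directional) PCA;
  $\lambda \to \infty$ forces $Sw \to 0$. There is no universally right
  value — it is selected by cross-validation (`cv_pmfa()`).
* $\|Sw\|_2^2$ spreads the steady-state violation across many metabolites
  in small amounts; $\|Sw\|_1$ concentrates it, zeroing most metabolite
  imbalances while tolerating a few outliers.
* $C$ (only for `loading_norm = 1`) controls sparsity: since
  $\|w\|_1 \le \sqrt{\|w\|_0}\,\|w\|_2$, small budgets force few active
  reactions.

## Algorithm

The objective is a difference of convex functions, so we use the
convex–concave procedure: at iterate $w_t$ the concave part
$-w^\top\Sigma w$ is linearized with its exact gradient $-2\Sigma w_t$,
and we solve the convex subproblem

$$\min_w\; \lambda\,\|Sw\|_q^{(2\ \mathrm{or}\ 1)}
   + \varepsilon\|w\|_2^2 - 2\,w_t^\top\Sigma w
 \qquad \text{s.t. } \|w\|_p \le C,\ w_{ir}\ge 0,$$

followed by projection of the minimizer back to the sphere
$\|w\|_p = C$. Two deliberate choices here:

* **Ball constraint.** The linearized objective alone is unbounded
  whenever the nullspace of `S` meets the feasible cone nontrivially (any
  steady mode could be scaled up indefinitely). Adding the ball
  $\|w\|_p \le C$ keeps every subproblem solvable and, at $\lambda = 0$,
  makes the iteration coincide exactly with projected power iteration.
* **Infinitesimal ridge.** The $\varepsilon\|w\|_2^2$ term
  (`ridge = 1e-10`) makes each subproblem strictly convex and tie-breaks
  coordinates with no objective incentive toward zero — this is what
  guarantees, e.g., that subsystem fits at $\lambda = 0$ have exact zeros
  outside the subsystem.

The subproblem is solved by the cheapest adequate method:

* $\lambda = 0$, $p = 2$: closed form (one power-iteration step, the
  linear objective maximized over the ball/cone).
* $q = 2$, $p = 2$, no directionality: an exact trust-region-style solve —
  eigendecomposition of $S^\top S$ (computed once per component) plus a
  one-dimensional root find on the ball multiplier.
* $q = 2$ otherwise: projected FISTA. The projection onto
  $\{\|w\|_p \le C\} \cap \{w_{ir} \ge 0\}$ is exact: clipping then
  rescaling for the $\ell_2$ ball; clipping then soft-thresholding with
  the sorted cumulative-sum threshold for the $\ell_1$ ball.
* $q = 1$: a Chambolle–Pock primal-dual scheme, handling $\|Sw\|_1$
  through its dual box constraint, with the same exact projection.

Projection back to the $\ell_1$ *sphere* is radial rescaling
($w \cdot C/\|w\|_1$), matching the `project_norm` contract; a Euclidean
alternative is selectable via `l1_projection = "euclidean"`.

The procedure is a local heuristic, so `solve_component()` runs
`n_restarts` random starts (standard normal; directionality-constrained
entries take absolute values; projected to the sphere) and keeps the best
objective. The default of 100 restarts is conservative for the network
sizes we target in-memory; the outer loop stops when the relative
objective change falls below `tol = 1e-6` (at most `max_iter = 200`
iterations). Restart $r$ is seeded with `seed + r`, and component $d$
offsets the seed by `1000 (d-1)`, so fits are reproducible bit for bit.

**Multi-factor models.** Loadings of successive components are not
orthogonal (the regularizer bends them), so "variance explained by the
next component" must be defined carefully. After accepting $w_d$ we extend
an orthonormal basis $Q$ by the Gram–Schmidt residual of $w_d$ and deflate
with the Schur complement
$\Sigma_{d+1} = \Sigma_d - \Sigma_d q_d q_d^\top \Sigma_d / (q_d^\top \Sigma_d q_d)$,
which removes all variance along $q_d$ and provably keeps $\Sigma_{d+1}$
positive semidefinite. The model reports both `variance_total` (against
the undeflated $\Sigma_1$) and `variance_additional` (against $\Sigma_d$);
the latter is nonincreasing in $d$.

**Hard steady state.** `hard = TRUE` imposes $Sw = 0$ exactly. Without
directionality this is an eigenproblem on an orthonormal nullspace basis
of `S` and is solved exactly; with directionality the feasible set is a
cone and no eigen-reduction exists, so we approximate with
$\lambda = 10^6$ and warn.

**Subsystems.** To analyze variance within a reaction subset (say, the
mitochondrial reactions) the covariance is embedded at the subsystem
coordinates (zeros elsewhere) while `S` and the directionality constraints
still span the whole network: the subsystem's variance may be carried by
pass-through fluxes outside it, and the regularizer must see those.
Degenerate corner: if the subsystem columns carry no variance at all,
every restart collapses and a flagged zero-objective component is
returned.

## Baselines

* `pca_components()` — dense eigensolver; with symmetric PSD input,
  projection deflation and eigenvector extraction coincide.
* `sparse_pca()` — the same CCP machinery with `S` replaced by the
  identity, so the penalty $\lambda\|w\|_1$ plays the sparsity role; with
  directionality this is directional sparse PCA.
* `fba()` — maximizes one reaction's flux under $Sw=0,\ l \le w \le u$.
  The LP is solved by a small dense two-phase simplex written for this
  package (Bland's rule, bounded variables by shifting/splitting), which
  is entirely adequate for the network sizes in scope and reports
  `infeasible` / `unbounded` as statuses rather than errors.
* `pema()` — greedy forward selection of elementary modes with per-sample
  nonnegative least-squares weights (`pracma::lsqnonneg`), residual-
  minimizing at each step, ties broken by lowest mode index. The input
  matrix is used *uncentered*: nonnegative weights on nonnegative modes
  can represent flux data exactly, but not column-centered data. Modes
  supported entirely on reversible reactions are tried in both
  orientations.

## Elementary modes and the simulator

`enumerate_ems()` implements double description on the split
(all-irreversible) cone $\{v \ge 0 : S_{split} v = 0\}$ with the
combinatorial adjacency test, removes the forward/backward two-cycle
artifacts of splitting, maps rays back to net fluxes, and re-verifies
support minimality pairwise. Enumeration is exponential in general; the
refusal cap (`max_reactions = 60` split columns) keeps it honest. A
brute-force oracle (all support subsets with one-dimensional nullspace)
confirms the enumeration on every fixture with at most 8 reactions.

`simulate_flux_data()` emulates a multi-condition fluxomics study: each
condition activates a fixed subset of elementary modes, and each sample is
a nonnegative random combination of its condition's active modes —
coefficients `Uniform(0.5, 2)` on unit-norm modes, a range chosen to give
order-one fluxes with a 4-fold spread while preserving cone membership.
Noise is applied entrywise afterwards. What this generator does *not*
emulate: correlated measurement error across reactions, systematic biases
of flux estimation pipelines, regulatory coupling between conditions, or
expression-to-flux nonlinearity. Passing tests on these data therefore
demonstrate correctness of the estimator under its own generative
assumptions, not performance on any particular experimental platform.

**Noise model.** The noise level is interpreted as a *relative standard
deviation*: entry $x$ receives $\mathcal N(0, (\text{level}\cdot|x|)^2)$,
and exact zeros stay zero. A literal relative-*variance* reading
($\sigma^2 = \text{level}\cdot|x|$) makes the perturbation's magnitude
depend on the measurement unit, which we consider unphysical as a
default; it remains available via `add_noise(mode =
"relative_variance")`.

**GPR mapping.** Boolean gene–protein–reaction rules map expression to
reactions with `or` → sum (isozymes add capacity) and `and` → elementwise
min (complex subunits limit capacity), applied recursively; `and` binds
tighter than `or` when parentheses are omitted. Missing genes error by
default (silent zeros hide data problems), with an explicit opt-in
`missing = "zero"` fallback.

## Evaluation choices

* `fraction_of_variance()` normalizes a single loading to unit $\ell_2$
  norm (so SPMFA loadings with $\|w\|_2 < 1$ are comparable) and
  orthonormalizes multi-component input, reporting
  $\mathrm{Tr}(Q^\top\Sigma Q)/\mathrm{Tr}(\Sigma)$ — the joint
  subspace fraction, not the sum of per-component fractions, which would
  double-count correlated loadings.
* `normalized_variance()` divides by $\|w\|_0/N_r$, counting an entry as
  nonzero when it exceeds `1e-6` times the largest magnitude.
* `em_retrieval()` scores each elementary mode by its maximum *absolute*
  Pearson correlation with any component (absolute, because of the sign
  indeterminacy without directionality), ranks by descending score with
  ties broken by lower index, and reports trapezoidal AUC and step-wise
  average precision (not PR-interpolated), so the numbers are exactly
  reproducible. Constant vectors get correlation 0, and an all-tied
  ranking is flagged degenerate.
* `cv_pmfa()` centers held-out folds with training-fold means — the
  test covariance of a leave-one-out fold is the rank-one matrix of the
  training-mean-centered sample. Fold assignment is seeded.

## Problem sizes used by the test and acceptance runs

The shipped checks run on: 20 random covariances up to dimension 30 for
the PCA limit; the 12-reaction `mini_ccm` fixture with 12 samples, 5%
noise and a 6-point $\lambda$ sweep for the regularization transition;
five replicate simulations with leave-one-out cross-validated $\lambda$
for mode retrieval; and a 40-reaction fixture with 24 samples and 4-fold
cross-validation for the sparse-vs-dense comparison. These sizes were
chosen so every property of interest is exercised at full strength while
a complete run stays interactive on one core; the statistics themselves
(monotone transition, retrieval AUC, normalized-variance advantage) are
scale-free.

## Known limitations

* The CCP is a local heuristic; multi-start mitigates but does not
  certify global optimality. All monotonicity statements (e.g. the
  $\lambda$-transition) hold at the *global* optimum and can be violated
  if a sweep point lands in a poor local one — more restarts are the
  remedy.
* Elementary-mode enumeration and PEMA are small-network tools by design.
* The simplex used by `fba()` is dense and unsuited to genome-scale
  models.
* SBML support covers Level 2/3 core plus fbc gene associations and flux
  bounds; kinetic laws, annotations and compartment semantics beyond the
  boundary flag are ignored.
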