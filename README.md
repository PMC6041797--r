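# pmfa: Principal Metabolic Flux Mode Analysis

`pmfa` extracts **principal metabolic flux modes** from fluxomic or
reaction-level expression data: loading vectors over the reactions of a
metabolic network that explain as much sample variance as possible while
staying close to a stoichiometric steady state. It is aimed at systems
biologists who want the exploratory power of PCA on multi-condition flux or
expression datasets without giving up the flux-mode structure of the
underlying network — and without enumerating elementary flux modes, which
is infeasible at genome scale.

## The model

Let `X` be the column-centered samples × reactions data matrix,
`Σ = (1/N) XᵀX` its covariance, and `S` the exchange stoichiometric matrix
over the internal metabolites. A principal metabolic flux mode solves

    max_w  wᵀΣw − λ ‖Sw‖²₂        (PMFA, l2 stoichiometric penalty)
    s.t.   w_ir ≥ 0 for irreversible reactions,  ‖w‖₂ = 1

`λ` tunes how hard the steady state `Sw = 0` is enforced: at `λ = 0` the
problem is (directional) PCA, as `λ → ∞` the loadings approach exact
steady-state flux modes. Variants: an `‖Sw‖₁` penalty that tolerates a few
strongly imbalanced metabolites (`stoich_norm = 1`); a sparse variant
**SPMFA** constraining `‖w‖₁ = C` so that modes involve few reactions
(`loading_norm = 1`); a hard-constrained mode (`hard = TRUE`); and
subsystem analysis, where the variance objective is restricted to a
reaction subset while the regularizer spans the whole network.

The objective is a difference of convex functions and is solved by a
multi-start convex–concave procedure: each iteration linearizes the
concave part and solves a ball-constrained convex subproblem, followed by
projection back to the norm sphere. Multi-factor models deflate the
covariance by the Schur complement along orthonormalized loadings, which
keeps it positive semidefinite and makes per-component *additional*
variance well defined.

The package also provides the surrounding toolkit: SBML and TSV network
input, gene–protein–reaction mapping of expression data (`or` → sum,
`and` → min), elementary-mode enumeration for small networks,
a steady-state flux simulator with a relative noise model, the baselines
PCA, sparse PCA, FBA and PEMA (greedy elementary-mode regression with
nonnegative weights), retrieval metrics (ROC/PR), and cross-validation
for `λ` and the sparsity budget.

## Worked example

```r
library(pmfa)

net <- make_toy_network("mini_ccm")     # 12-reaction central-carbon caricature
ems <- enumerate_ems(net)
ems
#> Elementary flux modes: 5 mode(s) over 12 reactions
#>   support sizes: 5, 4, 6, 4, 4

## simulate four conditions from three active modes, 5% relative noise
sim <- simulate_flux_data(ems, active_sets = list(1, 2, 3, c(1, 3)),
                          samples_per_condition = 3, noise = 0.05, seed = 1)

fit <- pmfa(sim$X, net, n_components = 2, lambda = 10,
            control = pmfa_control(n_restarts = 20, seed = 1))
summary(fit)
#> PMFA model with 2 component(s)
#>      variance additional frac_var    dev_sq nonzero
#> PMF1   0.3793     0.3793   0.4094 1.161e-04       8
#> PMF2   0.2827     0.2808   0.3050 3.893e-05       6
#> Joint fraction of variance (orthonormalized): 0.8535

em_retrieval(fit, ems, truth = 1:3)
#> Elementary-mode retrieval: AUC 1, AUPR 1
```

The two flux modes explain 85% of the sample variance jointly while being
essentially steady (`‖Sw‖²₂ ~ 1e-4`), and ranking all five elementary
modes by their correlation with the loadings puts the three truly active
modes first (AUC = 1).

`cv_pmfa()` selects `λ` (or the SPMFA budget `C`) by maximizing the
fraction of held-out variance; held-out folds are centered with training
means. A command-line front end with subcommands (`fit`, `pca`, `spca`,
`fba`, `pema`, `enumerate-ems`, `simulate`, `map-expression`, `evaluate`,
`cv`, `make-fixture`) is installed at
`system.file("cli", "pmfa.R", package = "pmfa")`.

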