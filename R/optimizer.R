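#' Solver configuration for PMFA / SPMFA
#'
#' Collects the hyper-parameters and numerical controls of the
#' convex-concave procedure (CCP) used by [pmfa()] and [solve_component()].
#'
#' @param lambda nonnegative steady-state regularization weight. Larger
#'   values pull the loadings toward the nullspace of `S` (steady state).
#' @param stoich_norm norm `q` on the steady-state deviation `S w`: `2`
#'   penalizes `||Sw||_2^2` (many small imbalances), `1` penalizes
#'   `||Sw||_1` (a few outlier metabolites allowed).
#' @param loading_norm norm `p` constraining the loadings: `2` gives dense
#'   flux modes on the unit sphere (PMFA), `1` gives sparse modes on the
#'   l1 sphere (SPMFA).
#' @param budget positive norm budget `C` with `||w||_p = C`; fixed to 1
#'   when `loading_norm = 2`.
#' @param directionality enforce `w_ir >= 0` on irreversible reactions.
#' @param n_restarts number of random CCP starts; the best local optimum is
#'   kept.
#' @param max_iter maximum CCP (outer) iterations per restart.
#' @param tol relative objective-change convergence tolerance of the outer
#'   loop.
#' @param seed integer master seed; restart `r` uses `seed + r`.
#' @param inner_max_iter iteration cap of the convex-subproblem solver.
#' @param inner_tol convergence tolerance of the subproblem solver.
#' @param ridge infinitesimal quadratic term added to each subproblem so
#'   coordinates with no objective incentive are tie-broken toward zero.
#' @param l1_projection how iterates are returned to the l1 sphere when
#'   `loading_norm = 1`: `"radial"` rescaling (default) or `"euclidean"`
#'   (closest point on the sphere obtained by projecting onto the l1 ball
#'   boundary).
#'
#' @return list of class `"pmfa_control"`.
#' @export
pmfa_control <- function(lambda = 1, stoich_norm = 2, loading_norm = 2,
                         budget = 1, directionality = TRUE,
                         n_restarts = 100, max_iter = 200, tol = 1e-6,
                         seed = 1L, inner_max_iter = 300, inner_tol = 1e-8,
                         ridge = 1e-10,
                         l1_projection = c("radial", "euclidean")) {
  stopifnot(lambda >= 0, stoich_norm %in% c(1, 2), loading_norm %in% c(1, 2),
            budget > 0, n_restarts >= 1, max_iter >= 1, tol > 0,
            inner_max_iter >= 1, inner_tol > 0, ridge >= 0)
  if (loading_norm == 2) budget <- 1
  structure(list(lambda = lambda, stoich_norm = stoich_norm,
                 loading_norm = loading_norm, budget = budget,
                 directionality = isTRUE(directionality),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed),
                 inner_max_iter = as.integer(inner_max_iter),
                 inner_tol = inner_tol, ridge = ridge,
                 l1_projection = match.arg(l1_projection)),
            class = "pmfa_control")
}

#' PMFA objective value
#'
#' `t(w) Sigma w - lambda * ||S w||_2^2` for `stoich_norm = 2`, or
#' `t(w) Sigma w - lambda * ||S w||_1` for `stoich_norm = 1`.
#'
#' @param w numeric loading vector.
#' @param Sigma covariance matrix.
#' @param S exchange stoichiometric matrix.
#' @param lambda nonnegative regularization weight.
#' @param stoich_norm 1 or 2.
#' @return scalar objective value.
#' @export
pmfa_objective <- function(w, Sigma, S, lambda, stoich_norm = 2) {
  if (length(w) != ncol(Sigma) || length(w) != ncol(S))
    stop("dimension mismatch between w, Sigma and S")
  sw <- drop(S %*% w)
  pen <- if (stoich_norm == 2) sum(sw^2) else sum(abs(sw))
  drop(crossprod(w, Sigma %*% w)) - lambda * pen
}

#' Project a vector radially onto the p-norm sphere of radius C
#'
#' @param w nonzero numeric vector.
#' @param p 1 or 2.
#' @param C positive radius.
#' @return `w * C / ||w||_p`.
#' @export
project_norm <- function(w, p = 2, C = 1) {
  nrm <- if (p == 2) sqrt(sum(w^2)) else sum(abs(w))
  if (nrm < 1e-300) stop("degenerate iterate: cannot project the zero vector")
  w * (C / nrm)
}

## Exact projection onto {||w||_p <= C} intersected with {w_i >= 0, i in
## nonneg}. For the centered l2 ball, clipping then rescaling is exact; for
## the l1 ball, clipping then soft-thresholding with the usual sorted
## cumulative-sum threshold is the KKT solution.
project_feasible <- function(x, p, C, nonneg) {
  y <- x
  if (length(nonneg)) y[nonneg] <- pmax(y[nonneg], 0)
  if (p == 2) {
    nrm <- sqrt(sum(y^2))
    if (nrm > C) y <- y * (C / nrm)
    return(y)
  }
  a <- abs(y)
  if (sum(a) <= C) return(y)
  u <- sort(a, decreasing = TRUE)
  cs <- cumsum(u)
  k <- max(which(u > (cs - C) / seq_along(u)))
  tau <- (cs[k] - C) / k
  sign(y) * pmax(a - tau, 0)
}

## Precomputations shared by all subproblem solves within one component.
ccp_prepare <- function(Sigma, S, control) {
  StS <- crossprod(S)
  prep <- list(StS = StS)
  if (control$stoich_norm == 2 && !control$directionality &&
      control$loading_norm == 2 && control$lambda > 0) {
    eg <- eigen(StS, symmetric = TRUE)
    prep$eigvec <- eg$vectors
    prep$eigval <- pmax(eg$values, 0)
  }
  ev <- eigen(StS, symmetric = TRUE, only.values = TRUE)$values
  prep$normS2 <- max(ev, 0)            # spectral norm squared of S
  prep
}

## Trust-region-style exact solve of min w'(lam S'S + eps I)w - g'w over the
## l2 ball ||w|| <= C, via the eigendecomposition of S'S and a 1-D root find
## on the ball multiplier.
trs_solve <- function(g, prep, lambda, eps, C) {
  gt <- drop(crossprod(prep$eigvec, g))
  d <- lambda * prep$eigval + eps
  wnorm <- function(mu) sqrt(sum((gt / (2 * (d + mu)))^2))
  if (wnorm(0) <= C) {
    w <- gt / (2 * d)
  } else {
    lo <- 0
    hi <- max(sqrt(sum(gt^2)) / (2 * C) - min(d), 1e-12)
    while (wnorm(hi) > C) hi <- hi * 2
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (wnorm(mid) > C) lo <- mid else hi <- mid
      if (hi - lo <= 1e-14 * (1 + hi)) break
    }
    w <- gt / (2 * (d + (lo + hi) / 2))
  }
  drop(prep$eigvec %*% w)
}

#' Convex subproblem of the convex-concave procedure
#'
#' Minimizes `lambda * ||S w||_q^(q==2 ? 2 : 1) + ridge * ||w||_2^2 -
#' 2 * t(w_t) Sigma w` over the feasible set `{||w||_p <= C}` intersected
#' with the directionality cone. The linear term is the exact linearization
#' of the concave part `-t(w) Sigma w` at the current iterate `w_t`. The
#' ball constraint keeps every subproblem bounded; the caller subsequently
#' projects back to the sphere `||w||_p = C`.
#'
#' Solved in closed form when `lambda = 0` and `p = 2` (one power-iteration
#' step), by an exact eigendecomposition-based ball-constrained quadratic
#' solve when `q = 2` without directionality and `p = 2`, by projected FISTA
#' when `q = 2` otherwise, and by a Chambolle-Pock primal-dual scheme when
#' `q = 1` (the `||Sw||_1` term is handled through its dual box constraint).
#'
#' @param w_t current iterate on the p-sphere.
#' @param Sigma covariance matrix (PSD).
#' @param S stoichiometric matrix.
#' @param control a [pmfa_control()].
#' @param nonneg integer indices of directionality-constrained reactions
#'   (empty when directionality is off).
#' @param prep optional precomputation from the internal preparation step;
#'   recomputed when `NULL`.
#' @return the subproblem minimizer (inside the ball; possibly zero when
#'   the iterate is degenerate).
#' @export
ccp_subproblem <- function(w_t, Sigma, S, control, nonneg = integer(0),
                           prep = NULL) {
  if (length(w_t) != ncol(Sigma) || length(w_t) != ncol(S))
    stop("dimension mismatch between w_t, Sigma and S")
  if (is.null(prep)) prep <- ccp_prepare(Sigma, S, control)
  g <- 2 * drop(Sigma %*% w_t)
  C <- control$budget
  p <- control$loading_norm
  eps <- control$ridge
  lam <- control$lambda

  if (lam == 0 && p == 2) {
    z <- g
    if (length(nonneg)) z[nonneg] <- pmax(z[nonneg], 0)
    nz <- sqrt(sum(z^2))
    if (nz < 1e-300) return(rep(0, length(w_t)))
    return(z * (C / nz))
  }

  if (control$stoich_norm == 2 && !length(nonneg) && p == 2 && lam > 0)
    return(trs_solve(g, prep, lam, eps, C))

  if (control$stoich_norm == 2) {
    ## projected FISTA on the smooth objective
    L <- 2 * lam * prep$normS2 + 2 * eps + 1e-12
    w <- project_feasible(w_t, p, C, nonneg)
    z <- w; tpar <- 1
    for (it in seq_len(control$inner_max_iter)) {
      grad <- 2 * lam * drop(prep$StS %*% z) + 2 * eps * z - g
      w_new <- project_feasible(z - grad / L, p, C, nonneg)
      t_new <- (1 + sqrt(1 + 4 * tpar^2)) / 2
      z <- w_new + ((tpar - 1) / t_new) * (w_new - w)
      if (max(abs(w_new - w)) <= control$inner_tol * max(1, C)) {
        w <- w_new; break
      }
      w <- w_new; tpar <- t_new
    }
    return(w)
  }

  ## q = 1: primal-dual (Chambolle-Pock) on
  ##   min_w  eps||w||^2 - g'w + lambda ||S w||_1 + indicator(feasible)
  nS <- sqrt(prep$normS2) + 1e-12
  sigma <- 0.99 / nS; tau <- 0.99 / nS
  w <- project_feasible(w_t, p, C, nonneg)
  wbar <- w
  y <- rep(0, nrow(S))
  for (it in seq_len(control$inner_max_iter)) {
    y <- pmin(pmax(y + sigma * drop(S %*% wbar), -lam), lam)
    w_new <- project_feasible(
      (w - tau * (drop(crossprod(S, y)) + 2 * eps * w - g)), p, C, nonneg)
    wbar <- 2 * w_new - w
    if (max(abs(w_new - w)) <= control$inner_tol * max(1, C) && it > 10) {
      w <- w_new; break
    }
    w <- w_new
  }
  w
}

#' Extract one principal metabolic flux mode by multi-start CCP
#'
#' Runs the convex-concave procedure from `n_restarts` random starting
#' points (standard normal draws; directionality-constrained entries take
#' absolute values; projected to the p-sphere) and returns the component
#' with the highest [pmfa_objective()]. Each restart alternates the convex
#' subproblem [ccp_subproblem()] with radial projection back to the sphere
#' until the relative objective change falls below `tol`.
#'
#' @param Sigma covariance matrix (symmetric PSD).
#' @param S stoichiometric matrix over the same reaction columns.
#' @param control a [pmfa_control()].
#' @param irreversible logical vector flagging irreversible reactions (used
#'   only when `control$directionality` is `TRUE`).
#' @return list of class `"pmfa_component"` with elements `w`, `objective`,
#'   `variance` (`t(w) Sigma w`), `deviation_sq` (`||Sw||_2^2`),
#'   `deviation_l1`, `iterations`, `best_restart`, `degenerate`.
#' @export
solve_component <- function(Sigma, S, control = pmfa_control(),
                            irreversible = rep(TRUE, ncol(Sigma))) {
  n <- ncol(Sigma)
  nonneg <- if (control$directionality) which(irreversible) else integer(0)
  prep <- ccp_prepare(Sigma, S, control)
  C <- control$budget; p <- control$loading_norm

  component <- function(w, obj, iters, restart, degenerate = FALSE) {
    if (!control$directionality && length(w) && any(w != 0)) {
      i <- which.max(abs(w))
      if (w[i] < 0) w <- -w
    }
    sw <- drop(S %*% w)
    structure(list(w = w, objective = obj,
                   variance = drop(crossprod(w, Sigma %*% w)),
                   deviation_sq = sum(sw^2), deviation_l1 = sum(abs(sw)),
                   iterations = iters, best_restart = restart,
                   degenerate = degenerate),
              class = "pmfa_component")
  }

  if (max(abs(Sigma)) < 1e-14 && control$lambda == 0) {
    w <- rep(0, n); w[1] <- C
    return(component(w, 0, 0L, 0L, degenerate = TRUE))
  }

  best <- NULL
  for (r in seq_len(control$n_restarts)) {
    set.seed(control$seed + r)
    w <- stats::rnorm(n)
    if (length(nonneg)) w[nonneg] <- abs(w[nonneg])
    w <- project_norm(w, p, C)
    obj <- pmfa_objective(w, Sigma, S, control$lambda, control$stoich_norm)
    iters <- 0L; failed <- FALSE
    for (t in seq_len(control$max_iter)) {
      iters <- t
      w_ball <- ccp_subproblem(w, Sigma, S, control, nonneg, prep)
      nrm <- if (p == 2) sqrt(sum(w_ball^2)) else sum(abs(w_ball))
      if (nrm < 1e-300) { failed <- TRUE; break }
      w_new <- if (control$l1_projection == "radial" || p == 2)
        project_norm(w_ball, p, C)
      else sphere_project_l1(w_ball, C, nonneg)
      obj_new <- pmfa_objective(w_new, Sigma, S, control$lambda,
                                control$stoich_norm)
      w <- w_new
      conv <- abs(obj_new - obj) <= control$tol * max(1, abs(obj))
      obj <- obj_new
      if (conv) break
    }
    if (failed) next
    if (is.null(best) || obj > best$objective)
      best <- list(w = w, objective = obj, iterations = iters, restart = r)
  }
  if (is.null(best)) {
    w <- rep(0, n); w[1] <- C
    return(component(w, pmfa_objective(w, Sigma, S, control$lambda,
                                       control$stoich_norm),
                     0L, 0L, degenerate = TRUE))
  }
  component(best$w, best$objective, best$iterations, best$restart)
}

## Euclidean projection onto the l1 sphere boundary (alternative to radial
## rescaling): project onto the l1 ball; when the point is strictly inside,
## push the largest coordinate out until the l1 norm reaches C.
sphere_project_l1 <- function(w, C, nonneg) {
  v <- project_feasible(w, 1, C, nonneg)
  nrm <- sum(abs(v))
  if (nrm >= C * (1 - 1e-12)) return(v * (C / max(nrm, 1e-300)))
  i <- which.max(abs(v))
  v[i] <- v[i] + sign(v[i] + (v[i] == 0)) * (C - nrm)
  v
}

#' @export
print.pmfa_component <- function(x, ...) {
  cat("PMF component: objective ", format(x$objective, digits = 6),
      ", variance ", format(x$variance, digits = 6),
      ", ||Sw||_2^2 ", format(x$deviation_sq, digits = 6),
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Extend an orthonormal basis by one loading vector
#'
#' Gram-Schmidt step: `q_d` is the unit-norm residual of `w_d` after
#' removing its projection onto the span of the previous basis vectors.
#'
#' @param Q_prev matrix with orthonormal columns (0 columns for the first
#'   component).
#' @param w_d new loading vector.
#' @return unit vector orthogonal to all columns of `Q_prev`.
#' @export
orthonormalize_next <- function(Q_prev, w_d) {
  if (sqrt(sum(w_d^2)) <= 0) stop("cannot orthonormalize a zero vector")
  r <- w_d
  if (!is.null(Q_prev) && NCOL(Q_prev) > 0) {
    Q_prev <- as.matrix(Q_prev)
    r <- w_d - Q_prev %*% crossprod(Q_prev, w_d)
  }
  nrm <- sqrt(sum(r^2))
  if (nrm < 1e-10)
    stop("linear dependence: new loading lies in the span of previous components")
  drop(r) / nrm
}

#' Schur-complement deflation of a covariance matrix
#'
#' `Sigma - Sigma q q' Sigma / (q' Sigma q)`. Unlike projection deflation
#' with non-orthogonal loadings, this removes all variance along `q` while
#' keeping the matrix positive semidefinite.
#'
#' @param Sigma symmetric PSD matrix.
#' @param q unit vector with `t(q) Sigma q > 1e-12`.
#' @return deflated symmetric PSD matrix with zero variance along `q`.
#' @export
schur_deflate <- function(Sigma, q) {
  sq <- drop(Sigma %*% q)
  denom <- drop(crossprod(q, sq))
  if (denom <= 1e-12)
    stop("no variance along q: cannot deflate (q' Sigma q <= 1e-12)")
  out <- Sigma - tcrossprod(sq) / denom
  (out + t(out)) / 2
}
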