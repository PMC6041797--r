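#' Principal components of a covariance matrix
#'
#' Ordinary PCA loadings: component `d` maximizes the variance of the
#' covariance deflated by the preceding components, i.e. the `d`-th unit
#' eigenvector. Signs follow the convention that the largest-magnitude
#' entry of each loading is positive.
#'
#' @param Sigma symmetric PSD matrix.
#' @param k number of components, `1 <= k <= ncol(Sigma)`.
#' @return list with `loadings` (`ncol(Sigma)` x `k`, unit columns) and
#'   `variances` (the corresponding eigenvalues).
#' @export
pca_components <- function(Sigma, k = 1) {
  if (k < 1 || k > ncol(Sigma)) stop("k out of range")
  eg <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  W <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- colnames(Sigma)
  list(loadings = W, variances = eg$values[seq_len(k)])
}

#' Sparse PCA component via the CCP machinery
#'
#' Maximizes `t(w) Sigma w - lambda_sparse * ||w||_1` subject to
#' `||w||_2 = 1`, optionally with nonnegativity on irreversible reactions
#' (directional sparse PCA). Internally this is the PMFA solver with the
#' stoichiometric matrix replaced by the identity, so the l1 penalty on
#' `S w` becomes the sparsity penalty on `w` itself.
#'
#' @param Sigma symmetric PSD matrix.
#' @param lambda_sparse nonnegative sparsity weight.
#' @param directionality enforce nonnegative loadings on irreversible
#'   reactions.
#' @param net a [metabolic_network()]; required when
#'   `directionality = TRUE` (reversibility flags); with `net = NULL` all
#'   reactions are treated as irreversible.
#' @param control a [pmfa_control()]; `lambda`, norms and budget are
#'   overridden internally.
#' @return a `"pmfa_component"` (see [solve_component()]).
#' @export
sparse_pca <- function(Sigma, lambda_sparse, directionality = FALSE,
                       net = NULL, control = pmfa_control()) {
  stopifnot(lambda_sparse >= 0)
  control$lambda <- lambda_sparse
  control$stoich_norm <- 1
  control$loading_norm <- 2
  control$budget <- 1
  control$directionality <- isTRUE(directionality)
  irrev <- if (!is.null(net)) !net$reversible else rep(TRUE, ncol(Sigma))
  solve_component(Sigma, diag(ncol(Sigma)), control, irreversible = irrev)
}

#' Flux balance analysis
#'
#' Maximizes the flux through one reaction subject to the steady-state
#' constraint `S w = 0` and the box constraints `l <= w <= u`, as a linear
#' program solved by a dense two-phase simplex. Intended for the small
#' networks in scope.
#'
#' @param net a [metabolic_network()].
#' @param objective_reaction reaction id whose flux is maximized.
#' @return list with `flux` (named optimal flux vector, `NULL` unless
#'   optimal), `value` (objective), `status` (`"optimal"`, `"infeasible"`
#'   or `"unbounded"`).
#' @export
fba <- function(net, objective_reaction) {
  j <- match(objective_reaction, net$reaction_ids)
  if (is.na(j)) stop("unknown objective reaction: ", objective_reaction)
  cc <- rep(0, length(net$reaction_ids)); cc[j] <- 1
  res <- lp_solve(cc, net$S, rep(0, nrow(net$S)), net$lb, net$ub)
  if (res$status != "optimal")
    return(list(flux = NULL, value = NA_real_, status = res$status))
  flux <- stats::setNames(res$x, net$reaction_ids)
  list(flux = flux, value = res$value, status = "optimal")
}

#' Principal elementary mode analysis (PEMA)
#'
#' Greedy forward selection of elementary modes: at each step, every unused
#' candidate mode is tentatively appended to the dictionary, nonnegative
#' per-sample weights are fit by NNLS, and the candidate giving the
#' smallest residual Frobenius norm of `X - Lambda t(P_em)` is kept (ties
#' broken by lowest mode index). Modes whose support lies entirely on
#' reversible reactions are tried in both orientations. `X` is used as
#' given (nonnegative weights require the flux scale, not centered data).
#'
#' @param X samples x reactions flux matrix aligned with the mode matrix.
#' @param ems an [enumerate_ems()] result (or any list with a `modes`
#'   matrix and the matching `network`).
#' @param k number of modes to select, `0 <= k <= ncol(ems$modes)`.
#' @return object of class `"pema"`: `selected` (ordered mode indices),
#'   `orientation` (+1/-1 per selected mode), `Lambda` (samples x k
#'   nonnegative weights), `residual_fro_sq` (path over steps 0..k),
#'   `explained_fraction` (per step).
#' @export
pema <- function(X, ems, k) {
  X <- as.matrix(X)
  M <- ems$modes
  if (ncol(X) != nrow(M)) stop("X and mode matrix are not aligned")
  if (k > ncol(M)) stop("k exceeds the number of elementary modes")
  net <- ems$network
  flip_ok <- vapply(seq_len(ncol(M)), function(j) {
    supp <- which(abs(M[, j]) > 1e-9)
    all(net$reversible[supp])
  }, logical(1))
  total <- sum(X^2)
  resid_path <- total
  selected <- integer(0)
  orientation <- numeric(0)
  Lambda <- NULL
  fit_resid <- function(P) {
    L <- t(apply(X, 1L, function(x) pracma::lsqnonneg(P, x)$x))
    if (ncol(P) == 1L) L <- matrix(L, ncol = 1L)
    list(L = L, resid = sum((X - L %*% t(P))^2))
  }
  for (step in seq_len(k)) {
    best <- NULL
    for (j in setdiff(seq_len(ncol(M)), selected)) {
      for (s in if (flip_ok[j]) c(1, -1) else 1) {
        P <- cbind(if (length(selected))
          sweep(M[, selected, drop = FALSE], 2L, orientation, `*`),
          s * M[, j])
        f <- fit_resid(P)
        if (is.null(best) || f$resid < best$resid - 1e-12) {
          best <- list(j = j, s = s, resid = f$resid, L = f$L)
        }
      }
    }
    selected <- c(selected, best$j)
    orientation <- c(orientation, best$s)
    Lambda <- best$L
    resid_path <- c(resid_path, best$resid)
  }
  structure(list(selected = selected, orientation = orientation,
                 Lambda = Lambda,
                 residual_fro_sq = resid_path,
                 explained_fraction = if (total > 0) 1 - resid_path / total
                 else rep(NA_real_, length(resid_path))),
            class = "pema")
}

#' @export
print.pema <- function(x, ...) {
  cat("PEMA: ", length(x$selected), " elementary mode(s) selected: ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  cat("  residual ||E||_F^2 path: ",
      paste(format(x$residual_fro_sq, digits = 4), collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}
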