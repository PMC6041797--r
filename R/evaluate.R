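#' Fraction of variance explained by loadings
#'
#' `t(w) Sigma w / Trace(Sigma)` for a single loading vector (normalized to
#' unit Euclidean norm first, so the value is scale-free and lies in
#' `[0, 1]` for PSD `Sigma`). For a matrix of loadings the columns are
#' orthonormalized and the value is `Trace(t(Q) Sigma Q) / Trace(Sigma)`.
#'
#' @param w loading vector or reactions x components matrix.
#' @param Sigma covariance matrix (typically of held-out samples).
#' @return scalar fraction.
#' @export
fraction_of_variance <- function(w, Sigma) {
  tr <- sum(diag(Sigma))
  if (tr <= 0) stop("Trace(Sigma) must be positive")
  if (is.matrix(w) && ncol(w) > 1L) {
    Q <- qr.Q(qr(w))[, seq_len(qr(w)$rank), drop = FALSE]
    return(sum(diag(crossprod(Q, Sigma %*% Q))) / tr)
  }
  w <- drop(w)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("zero loading vector")
  w <- w / nrm
  drop(crossprod(w, Sigma %*% w)) / tr
}

#' Variance fraction normalized by loading sparsity
#'
#' [fraction_of_variance()] divided by the fraction of nonzero loadings
#' `||w||_0 / N_r`, where an entry counts as nonzero when its magnitude
#' exceeds `zero_tol` times the largest magnitude. Rewards components that
#' explain variance with few reactions.
#'
#' @param w loading vector.
#' @param Sigma covariance matrix.
#' @param zero_tol relative zero threshold (default `1e-6`).
#' @return scalar normalized variance.
#' @export
normalized_variance <- function(w, Sigma, zero_tol = 1e-6) {
  w <- drop(w)
  mx <- max(abs(w))
  if (mx == 0) stop("zero loading vector")
  l0 <- sum(abs(w) > zero_tol * mx)
  fraction_of_variance(w, Sigma) / (l0 / length(w))
}

#' Elementary-mode retrieval curves for a fitted model
#'
#' Scores each elementary mode by its maximum absolute Pearson correlation
#' with any of the model's loading vectors, ranks modes by descending score
#' (ties broken by lower index), and computes precision, recall, TPR and
#' FPR at every rank against the ground-truth active set. AUC is the
#' trapezoidal area under the ROC curve; AUPR is the step-wise average
#' precision. Absolute correlation is used because loadings carry a sign
#' indeterminacy when directionality is off. Constant (zero-variance)
#' vectors get correlation 0.
#'
#' @param components loading vector, matrix (columns = components), or a
#'   fitted [pmfa()] model.
#' @param ems an [enumerate_ems()] result (or a matrix of modes).
#' @param truth integer indices of the ground-truth active modes; must be
#'   nonempty and a proper subset of all modes.
#' @return object of class `"em_retrieval"`: `ranked` (mode indices in
#'   rank order), `score` (per mode), `precision`, `recall`, `tpr`, `fpr`
#'   (per rank), `auc`, `aupr`, `degenerate` (all scores tied).
#' @export
em_retrieval <- function(components, ems, truth) {
  if (inherits(components, "pmfa")) components <- components$loadings
  W <- as.matrix(components)
  M <- if (is.matrix(ems)) ems else ems$modes
  n_em <- ncol(M)
  truth <- sort(unique(as.integer(truth)))
  if (!length(truth) || length(truth) >= n_em)
    stop("truth must be a nonempty proper subset of the modes")
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  score <- vapply(seq_len(n_em), function(j)
    max(vapply(seq_len(ncol(W)), function(k)
      abs(safe_cor(W[, k], M[, j])), numeric(1))), numeric(1))
  ranked <- order(-score, seq_len(n_em))
  is_pos <- ranked %in% truth
  tp <- cumsum(is_pos)
  fp <- cumsum(!is_pos)
  P <- length(truth); Np <- n_em - P
  precision <- tp / seq_len(n_em)
  recall <- tp / P
  tpr <- recall
  fpr <- fp / Np
  auc <- sum(diff(c(0, fpr)) * (utils::head(c(0, tpr), -1) +
                                utils::tail(c(0, tpr), -1)) / 2)
  aupr <- sum(diff(c(0, recall)) * precision)
  structure(list(ranked = ranked, score = score, precision = precision,
                 recall = recall, tpr = tpr, fpr = fpr,
                 auc = auc, aupr = aupr,
                 degenerate = length(unique(score)) == 1L),
            class = "em_retrieval")
}

#' @export
print.em_retrieval <- function(x, ...) {
  cat("Elementary-mode retrieval: AUC ", format(x$auc, digits = 4),
      ", AUPR ", format(x$aupr, digits = 4),
      if (x$degenerate) " [degenerate: all scores tied]", "\n", sep = "")
  invisible(x)
}

#' Cross-validated selection of PMFA hyper-parameters
#'
#' For every row of the parameter grid, fits the model on each training
#' fold and evaluates the fraction of held-out variance explained by the
#' (orthonormalized) loadings; held-out samples are centered with the
#' *training* column means so no information leaks. Returns the grid
#' annotated with mean test fractions and the best row.
#'
#' @param X samples x reactions matrix.
#' @param net a [metabolic_network()].
#' @param grid data frame whose columns are a subset of `lambda`,
#'   `stoich_norm`, `loading_norm`, `budget`, `directionality`; one model
#'   per row.
#' @param scheme `"loo"` or an integer number of folds.
#' @param n_components components per model.
#' @param control baseline [pmfa_control()] for all grid points.
#' @param seed seed for the fold assignment.
#' @param subsystem optional subsystem passed to [pmfa()].
#' @return list of class `"pmfa_cv"`: `table` (grid plus
#'   `mean_test_frac`), `best` (row index of the maximum), `best_params`
#'   (that row as a list), `folds` (assignment vector).
#' @export
cv_pmfa <- function(X, net, grid, scheme = "loo", n_components = 1,
                    control = pmfa_control(), seed = 1L, subsystem = NULL) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (!nrow(grid)) stop("empty parameter grid")
  if (identical(scheme, "loo")) {
    folds <- seq_len(N)
  } else {
    kf <- as.integer(scheme)
    if (N < kf) stop("fewer samples than folds")
    set.seed(seed)
    folds <- sample(rep(seq_len(kf), length.out = N))
  }
  n_folds <- length(unique(folds))
  mean_frac <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    ctl <- control
    for (nm in intersect(names(grid),
                         c("lambda", "stoich_norm", "loading_norm",
                           "budget", "directionality")))
      ctl[[nm]] <- grid[[nm]][gidx]
    if (ctl$loading_norm == 2) ctl$budget <- 1
    fracs <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- pmfa(X[tr, , drop = FALSE], net, n_components = n_components,
                  subsystem = subsystem, control = ctl)
      mu <- fit$column_means
      Xte <- sweep(X[!tr, , drop = FALSE], 2L, mu, `-`)
      Sig_te <- crossprod(Xte) / nrow(Xte)
      W <- fit$loadings
      fracs[f] <- if (sum(diag(Sig_te)) <= 0) 0 else
        fraction_of_variance(W, Sig_te)
    }
    mean_frac[gidx] <- mean(fracs)
  }
  best <- which.max(mean_frac)
  structure(list(table = cbind(grid, mean_test_frac = mean_frac),
                 best = best, best_params = as.list(grid[best, , drop = FALSE]),
                 folds = folds),
            class = "pmfa_cv")
}

#' @export
print.pmfa_cv <- function(x, ...) {
  cat("PMFA cross-validation over", nrow(x$table), "grid point(s)\n")
  print(format(x$table, digits = 4))
  cat("selected row:", x$best, "\n")
  invisible(x)
}
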