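#' Center the columns of a data matrix
#'
#' Subtracts per-column means (or supplied means, e.g. training-fold means
#' when centering held-out data) and records them in the `"column_means"`
#' attribute so the operation can be undone or reapplied.
#'
#' @param X numeric samples x reactions (or genes) matrix.
#' @param means optional numeric vector of means to subtract instead of the
#'   empirical column means.
#' @return centered matrix with attribute `column_means`.
#' @export
center_columns <- function(X, means = NULL) {
  X <- as.matrix(X)
  if (is.null(means)) means <- colMeans(X)
  if (length(means) != ncol(X)) stop("length(means) != ncol(X)")
  Xc <- sweep(X, 2L, means, `-`)
  attr(Xc, "column_means") <- as.numeric(means)
  Xc
}

#' Empirical covariance of a centered data matrix
#'
#' Returns `Sigma = (1/N) t(X) %*% X`, the maximum-likelihood covariance of
#' column-centered data; symmetric and positive semidefinite by
#' construction.
#'
#' @param X centered numeric samples x variables matrix.
#' @param check if `TRUE` (default), error when any column mean exceeds
#'   `1e-8` in magnitude (the matrix is not centered).
#' @return symmetric `ncol(X)` x `ncol(X)` covariance matrix.
#' @export
flux_covariance <- function(X, check = TRUE) {
  X <- as.matrix(X)
  if (check && nrow(X) > 1L && max(abs(colMeans(X))) > 1e-8)
    stop("data matrix is not column-centered; call center_columns() first")
  Sigma <- crossprod(X) / nrow(X)
  (Sigma + t(Sigma)) / 2
}
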