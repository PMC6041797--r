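## Independent oracles and fixture builders used across the test files.

random_psd <- function(n, seed, rank = n) {
  set.seed(seed)
  A <- matrix(rnorm(n * rank), rank, n)
  crossprod(A) / rank
}

## entrywise two-loop covariance of centered data
naive_covariance <- function(X) {
  N <- nrow(X); p <- ncol(X)
  S <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    s <- 0
    for (k in seq_len(N)) s <- s + X[k, i] * X[k, j]
    S[i, j] <- s / N
  }
  S
}

## brute-force elementary-mode oracle: every support subset whose restricted
## stoichiometry has a one-dimensional nullspace, sign-feasible on
## irreversible reactions, support exactly the subset; then minimality.
brute_force_ems <- function(net, tol = 1e-9) {
  n <- length(net$reaction_ids)
  cands <- list()
  for (size in seq_len(n)) {
    for (J in utils::combn(n, size, simplify = FALSE)) {
      SJ <- net$S[, J, drop = FALSE]
      ns <- MASS::Null(t(SJ))
      if (is.null(dim(ns)) || ncol(ns) != 1L) next
      v <- drop(ns)
      if (any(abs(v) <= tol)) next          # support must be exactly J
      full <- numeric(n); full[J] <- v
      ir <- !net$reversible
      if (all(full[ir] >= -tol)) {
      } else if (all((-full)[ir] >= -tol)) {
        full <- -full
      } else next
      if (all(!ir[J])) {                    # sign-flippable: canonical sign
        if (full[J[1]] < 0) full <- -full
      }
      cands[[length(cands) + 1L]] <- full / sqrt(sum(full^2))
    }
  }
  if (!length(cands)) return(matrix(0, n, 0))
  M <- do.call(cbind, cands)
  M <- M[, !duplicated(round(t(M), 8)), drop = FALSE]
  supp <- apply(M, 2L, function(v) which(abs(v) > 1e-8), simplify = FALSE)
  keep <- rep(TRUE, ncol(M))
  for (i in seq_along(supp)) for (j in seq_along(supp)) {
    if (i != j && length(supp[[j]]) < length(supp[[i]]) &&
        all(supp[[j]] %in% supp[[i]])) keep[i] <- FALSE
  }
  M[, keep, drop = FALSE]
}

## two mode matrices are equal up to column order, scaling and allowed sign
expect_same_mode_set <- function(A, B, net, tol = 1e-6) {
  expect_equal(ncol(A), ncol(B))
  normalize <- function(M) {
    M <- sweep(M, 2L, sqrt(colSums(M^2)), `/`)
    for (j in seq_len(ncol(M))) {
      supp <- which(abs(M[, j]) > 1e-8)
      if (all(net$reversible[supp]) && M[supp[1], j] < 0) M[, j] <- -M[, j]
    }
    M
  }
  A <- normalize(as.matrix(A)); B <- normalize(as.matrix(B))
  used <- rep(FALSE, ncol(B))
  for (j in seq_len(ncol(A))) {
    d <- vapply(seq_len(ncol(B)), function(k)
      if (used[k]) Inf else max(abs(A[, j] - B[, k])), numeric(1))
    k <- which.min(d)
    expect_lt(d[k], tol)
    used[k] <- TRUE
  }
}

## all-thresholds ROC/PR oracle (assumes untied scores)
auc_oracle <- function(score, truth_idx) {
  n <- length(score)
  pos <- seq_len(n) %in% truth_idx
  ths <- sort(unique(score), decreasing = TRUE)
  tpr <- fpr <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- score >= ths[i]
    tpr[i] <- sum(pred & pos) / sum(pos)
    fpr[i] <- sum(pred & !pos) / sum(!pos)
  }
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

aupr_oracle <- function(score, truth_idx) {
  n <- length(score)
  pos <- seq_len(n) %in% truth_idx
  ord <- order(-score)
  ap <- 0; tp <- 0
  for (i in seq_len(n)) {
    if (pos[ord[i]]) {
      tp <- tp + 1
      ap <- ap + tp / i
    }
  }
  ap / sum(pos)
}

## quick mini_ccm simulation shared by several tests
mini_ccm_sim <- function(noise = 0.05, seed = 1, n_cond = 12,
                         active = list(1, 2, 3)) {
  net <- make_toy_network("mini_ccm")
  ems <- enumerate_ems(net)
  set.seed(seed)
  sets <- lapply(seq_len(n_cond), function(i) {
    pool <- unlist(active)
    sort(sample(pool, sample(seq_along(pool), 1)))
  })
  sim <- simulate_flux_data(ems, sets, samples_per_condition = 1,
                            noise = noise, seed = seed)
  list(net = net, ems = ems, sim = sim)
}

fast_control <- function(...) {
  args <- list(...)
  if (is.null(args$n_restarts)) args$n_restarts <- 10
  do.call(pmfa_control, args)
}
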