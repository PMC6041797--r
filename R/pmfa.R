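#' Principal metabolic flux mode analysis
#'
#' Fits a multi-factor PMFA (or sparse SPMFA) model: each component
#' (principal metabolic flux mode, PMF) maximizes the explained sample
#' variance `t(w) Sigma w` penalized by its deviation from stoichiometric
#' steady state, `lambda * ||S w||_q^(2 or 1)`, subject to a p-norm
#' constraint on the loadings and optionally nonnegativity on irreversible
#' reactions. Components are extracted sequentially; after each one the
#' covariance is deflated by the Schur complement along the orthonormalized
#' loading directions so that subsequent components capture *additional*
#' variance.
#'
#' With `lambda = 0`, `stoich_norm = loading_norm = 2` and
#' `directionality = FALSE` the model coincides with PCA. `hard = TRUE`
#' imposes the exact steady-state constraint `S w = 0` instead of the
#' penalty (solved by PCA restricted to an orthonormal nullspace basis of
#' `S`; with directionality this is approximated by `lambda = 1e6` with a
#' warning, since the constrained problem is no longer an eigenproblem).
#'
#' @param X numeric samples x reactions matrix. When it has column names
#'   they must match (a superset of the subsystem of) the network's
#'   reaction ids and are used for alignment; otherwise columns are taken
#'   in network order.
#' @param network a [metabolic_network()].
#' @param n_components number of flux modes to extract.
#' @param lambda,stoich_norm,loading_norm,budget,directionality see
#'   [pmfa_control()]; given here for convenience, they override `control`.
#' @param subsystem optional subsystem label or reaction-id vector (see
#'   [subsystem_columns()]): the variance objective is restricted to these
#'   reactions (covariance embedded at the subsystem coordinates, zero
#'   elsewhere) while the stoichiometric regularizer still spans the whole
#'   network.
#' @param hard impose `S w = 0` exactly instead of the soft penalty.
#' @param center column-center `X` before computing the covariance
#'   (training means are stored for use by [predict.pmfa()]).
#' @param control a [pmfa_control()] with the remaining solver settings.
#' @return An object of class `"pmfa"`: list with `loadings` (reactions x
#'   components matrix `W`), `components` (per-component solver output,
#'   see [solve_component()]), `Q` (orthonormalized loadings),
#'   `variance_total` (per component, `t(w) Sigma_1 w` against the
#'   undeflated covariance), `variance_additional` (against the deflated
#'   covariance it was extracted from), `deviation_sq`, `Sigma`,
#'   `column_means`, `control`, `network`, `call`.
#' @seealso [pca_components()], [sparse_pca()], [pema()], [cv_pmfa()]
#' @examples
#' net <- make_toy_network("branched")
#' ems <- enumerate_ems(net)
#' sim <- simulate_flux_data(ems, active_sets = list(1, 2),
#'                           samples_per_condition = 6, seed = 1)
#' fit <- pmfa(sim$X, net, n_components = 2, lambda = 10,
#'             control = pmfa_control(n_restarts = 10))
#' fit
#' @export
pmfa <- function(X, network, n_components = 1,
                 lambda = NULL, stoich_norm = NULL, loading_norm = NULL,
                 budget = NULL, directionality = NULL,
                 subsystem = NULL, hard = FALSE, center = TRUE,
                 control = pmfa_control()) {
  cl <- match.call()
  if (!is.null(lambda)) control$lambda <- lambda
  if (!is.null(stoich_norm)) control$stoich_norm <- stoich_norm
  if (!is.null(loading_norm)) control$loading_norm <- loading_norm
  if (!is.null(budget) && control$loading_norm == 1) control$budget <- budget
  if (!is.null(directionality)) control$directionality <- isTRUE(directionality)

  net <- network
  n_r <- length(net$reaction_ids)
  X <- as.matrix(X)
  sub_idx <- if (!is.null(subsystem)) subsystem_columns(net, subsystem) else NULL

  ## align data columns with the network by reaction id
  if (!is.null(colnames(X))) {
    pos <- match(colnames(X), net$reaction_ids)
    if (anyNA(pos))
      stop("data columns not in network: ",
           paste(utils::head(colnames(X)[is.na(pos)], 5), collapse = ", "))
  } else {
    if (ncol(X) != n_r)
      stop("unnamed data matrix must have one column per network reaction")
    pos <- seq_len(n_r)
  }
  need <- if (is.null(sub_idx)) seq_len(n_r) else sub_idx
  if (!all(need %in% pos))
    stop("data matrix must provide columns for ",
         if (is.null(sub_idx)) "all reactions" else "the whole subsystem")

  means <- rep(0, ncol(X))
  if (center) {
    X <- center_columns(X)
    means <- attr(X, "column_means")
  }
  Sig_meas <- flux_covariance(X, check = center)

  ## embed the (possibly partial, possibly subsystem-restricted) covariance
  ## at the network coordinates; regularizer always spans all reactions
  Sigma1 <- matrix(0, n_r, n_r,
                   dimnames = list(net$reaction_ids, net$reaction_ids))
  keep <- if (is.null(sub_idx)) seq_along(pos) else which(pos %in% sub_idx)
  Sigma1[pos[keep], pos[keep]] <- Sig_meas[keep, keep]

  S <- net$S
  if (hard) {
    if (control$directionality) {
      warning("hard steady state with directionality is approximated by ",
              "lambda = 1e6")
      control$lambda <- 1e6
    } else {
      return(pmfa_hard_fit(Sigma1, S, net, n_components, control, means,
                           pos, cl))
    }
  }

  comps <- vector("list", n_components)
  W <- matrix(0, n_r, 0)
  Q <- matrix(0, n_r, 0)
  var_tot <- var_add <- dev_sq <- numeric(0)
  Sigma_d <- Sigma1
  ctl <- control
  for (d in seq_len(n_components)) {
    ctl$seed <- control$seed + 1000L * (d - 1L)
    comp <- solve_component(Sigma_d, S, ctl, irreversible = !net$reversible)
    comps[[d]] <- comp
    W <- cbind(W, comp$w)
    var_tot <- c(var_tot, drop(crossprod(comp$w, Sigma1 %*% comp$w)))
    var_add <- c(var_add, comp$variance)
    dev_sq <- c(dev_sq, comp$deviation_sq)
    if (d < n_components) {
      q_d <- tryCatch(orthonormalize_next(Q, comp$w), error = function(e) NULL)
      if (is.null(q_d)) {
        warning("component ", d, " linearly dependent on previous ones; ",
                "stopping after ", d, " components")
        comps <- comps[seq_len(d)]
        break
      }
      Q <- cbind(Q, q_d)
      Sigma_d <- schur_deflate(Sigma_d, q_d)
    } else {
      q_d <- tryCatch(orthonormalize_next(Q, comp$w), error = function(e) NULL)
      if (!is.null(q_d)) Q <- cbind(Q, q_d)
    }
  }
  rownames(W) <- net$reaction_ids
  colnames(W) <- paste0("PMF", seq_len(ncol(W)))
  structure(list(loadings = W, components = comps, Q = Q,
                 variance_total = var_tot, variance_additional = var_add,
                 deviation_sq = dev_sq, Sigma = Sigma1,
                 column_means = means, data_columns = pos,
                 subsystem = sub_idx, hard = hard,
                 control = control, network = net, call = cl),
            class = "pmfa")
}

## exact hard-constrained fit: PCA on an orthonormal nullspace basis of S
pmfa_hard_fit <- function(Sigma1, S, net, n_components, control, means,
                          pos, cl) {
  n_r <- ncol(S)
  sv <- svd(S, nu = 0, nv = n_r)
  tolr <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  null_idx <- which(c(sv$d, rep(0, n_r - length(sv$d))) <= tolr)
  if (!length(null_idx)) stop("S has a trivial nullspace: no steady-state mode")
  K <- sv$v[, null_idx, drop = FALSE]
  B <- crossprod(K, Sigma1 %*% K)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  k <- min(n_components, ncol(K))
  W <- K %*% eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  comps <- lapply(seq_len(k), function(j) {
    w <- W[, j]
    sw <- drop(S %*% w)
    structure(list(w = w, objective = eg$values[j], variance = eg$values[j],
                   deviation_sq = sum(sw^2), deviation_l1 = sum(abs(sw)),
                   iterations = 0L, best_restart = 0L, degenerate = FALSE),
              class = "pmfa_component")
  })
  rownames(W) <- net$reaction_ids
  colnames(W) <- paste0("PMF", seq_len(k))
  structure(list(loadings = W, components = comps, Q = W,
                 variance_total = vapply(comps, `[[`, 0, "variance"),
                 variance_additional = vapply(comps, `[[`, 0, "variance"),
                 deviation_sq = vapply(comps, `[[`, 0, "deviation_sq"),
                 Sigma = Sigma1, column_means = means, data_columns = pos,
                 subsystem = NULL, hard = TRUE,
                 control = control, network = net, call = cl),
            class = "pmfa")
}

#' @export
print.pmfa <- function(x, ...) {
  d <- ncol(x$loadings)
  cat("Principal metabolic flux mode analysis\n")
  cat("  ", d, " component(s), lambda = ", x$control$lambda,
      ", stoich norm l", x$control$stoich_norm,
      ", loading norm l", x$control$loading_norm,
      if (x$control$directionality) ", directionality on" else "",
      if (x$hard) ", hard steady state" else "", "\n", sep = "")
  tr <- sum(diag(x$Sigma))
  tab <- data.frame(
    variance = x$variance_total,
    frac_var = if (tr > 0) x$variance_total / tr else NA,
    dev_sq = x$deviation_sq,
    row.names = colnames(x$loadings))
  print(format(tab, digits = 4))
  invisible(x)
}

#' @export
summary.pmfa <- function(object, zero_tol = 1e-6, ...) {
  tr <- sum(diag(object$Sigma))
  W <- object$loadings
  l0 <- apply(W, 2, function(w) sum(abs(w) > zero_tol * max(abs(w))))
  out <- list(
    n_components = ncol(W),
    control = object$control,
    table = data.frame(
      variance = object$variance_total,
      additional = object$variance_additional,
      frac_var = if (tr > 0) object$variance_total / tr else NA,
      dev_sq = object$deviation_sq,
      nonzero = l0,
      row.names = colnames(W)),
    joint_frac = if (tr > 0 && ncol(object$Q) > 0)
      sum(diag(crossprod(object$Q, object$Sigma %*% object$Q))) / tr else NA)
  class(out) <- "summary.pmfa"
  out
}

#' @export
print.summary.pmfa <- function(x, ...) {
  cat("PMFA model with", x$n_components, "component(s)\n")
  print(format(x$table, digits = 4))
  cat("Joint fraction of variance (orthonormalized):",
      format(x$joint_frac, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.pmfa <- function(object, ...) object$loadings

#' Project new samples onto fitted flux modes
#'
#' Centers `newdata` with the training column means and returns the sample
#' scores on the loadings.
#'
#' @param object a fitted [pmfa()] model.
#' @param newdata samples x reactions matrix (defaults to refusing; scores
#'   of the training data are not stored).
#' @param orthonormal use the orthonormalized basis `Q` instead of the raw
#'   loadings.
#' @param ... unused.
#' @return samples x components score matrix.
#' @export
predict.pmfa <- function(object, newdata, orthonormal = FALSE, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    pos <- match(object$network$reaction_ids, colnames(X))
    if (anyNA(pos)) stop("newdata lacks reaction columns: ",
                         paste(utils::head(
                           object$network$reaction_ids[is.na(pos)], 5),
                           collapse = ", "))
    X <- X[, pos, drop = FALSE]
    mu <- object$column_means[match(pos, object$data_columns)]
    mu[is.na(mu)] <- 0
  } else {
    if (ncol(X) != nrow(object$loadings))
      stop("newdata must have one column per network reaction")
    mu <- rep(0, ncol(X))
    mu[object$data_columns] <- object$column_means
  }
  Xc <- sweep(X, 2L, mu, `-`)
  B <- if (orthonormal) object$Q else object$loadings
  scores <- Xc %*% B
  colnames(scores) <- colnames(object$loadings)[seq_len(ncol(scores))]
  scores
}

#' @export
residuals.pmfa <- function(object, newdata, ...) {
  if (missing(newdata)) stop("supply the data matrix to compute residuals for")
  X <- as.matrix(newdata)
  mu <- rep(0, ncol(X)); mu[object$data_columns] <- object$column_means
  Xc <- sweep(X, 2L, mu, `-`)
  Q <- object$Q
  Xc - (Xc %*% Q) %*% t(Q)
}

#' Plot a fitted PMFA model
#'
#' `type = "loadings"` draws a barplot of the selected component's loadings
#' by reaction; `type = "variance"` a scree-style plot of the per-component
#' fraction of variance.
#'
#' @param x a fitted [pmfa()] model.
#' @param type `"loadings"` or `"variance"`.
#' @param component which component to draw for `type = "loadings"`.
#' @param ... passed to the underlying base graphics call.
#' @export
plot.pmfa <- function(x, type = c("loadings", "variance"), component = 1, ...) {
  type <- match.arg(type)
  if (type == "loadings") {
    w <- x$loadings[, component]
    graphics::barplot(w, las = 2, ylab = "loading",
                      main = colnames(x$loadings)[component], ...)
  } else {
    tr <- sum(diag(x$Sigma))
    graphics::plot(seq_along(x$variance_total), x$variance_total / tr,
                   type = "b", xlab = "component",
                   ylab = "fraction of variance", ...)
  }
  invisible(x)
}

#' Serialize a fitted model to JSON and CSV
#'
#' Writes `<name>.json` (configuration plus per-component loadings keyed by
#' reaction id, objective, variance and steady-state deviations) and
#' `<name>_loadings.csv` (reactions x components table) into `dir`.
#'
#' @param model a fitted [pmfa()] model.
#' @param dir output directory (created if needed).
#' @param name file stem, default `"pmfa_model"`.
#' @return invisibly, the path of the JSON file.
#' @export
write_pmfa <- function(model, dir, name = "pmfa_model") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comps <- lapply(seq_along(model$components), function(d) {
    cmp <- model$components[[d]]
    list(loadings = as.list(stats::setNames(cmp$w, model$network$reaction_ids)),
         objective = cmp$objective, variance = cmp$variance,
         deviation_sq = cmp$deviation_sq, deviation_l1 = cmp$deviation_l1)
  })
  doc <- list(config = unclass(model$control), components = comps)
  json_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  df <- data.frame(reaction_id = model$network$reaction_ids,
                   model$loadings, check.names = FALSE)
  utils::write.csv(df, file.path(dir, paste0(name, "_loadings.csv")),
                   row.names = FALSE)
  invisible(json_path)
}
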