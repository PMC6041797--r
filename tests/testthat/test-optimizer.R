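test_that("objective value follows the penalized variance formula", {
  Sig <- diag(c(2, 1))
  S <- matrix(c(1, -1), 1, 2)
  expect_equal(pmfa_objective(c(1, 0), Sig, S, lambda = 3, stoich_norm = 2),
               2 - 3 * 1)
  expect_equal(pmfa_objective(c(1, 0), Sig, S, lambda = 3, stoich_norm = 1),
               2 - 3 * 1)
  ## lambda = 0 reduces to the variance
  w <- c(0.6, 0.8)
  expect_equal(pmfa_objective(w, Sig, S, 0, 2),
               drop(crossprod(w, Sig %*% w)))
  ## nullspace vectors are unpenalized for any lambda
  wn <- c(1, 1) / sqrt(2)
  expect_equal(pmfa_objective(wn, Sig, S, 50, 2),
               drop(crossprod(wn, Sig %*% wn)))
  expect_error(pmfa_objective(c(1, 0, 0), Sig, S, 1), "dimension")
})

test_that("radial norm projection lands exactly on the sphere", {
  expect_equal(project_norm(c(3, 4), 2, 1), c(0.6, 0.8))
  expect_equal(project_norm(c(1, 1), 1, 4), c(2, 2))
  w <- project_norm(rnorm(5), 1, 2.5)
  expect_equal(project_norm(w, 1, 2.5), w)
  expect_error(project_norm(c(0, 0), 2, 1), "zero vector")
})

test_that("subproblem at lambda = 0 is one power-iteration step", {
  set.seed(31)
  Sig <- random_psd(6, 31)
  S <- matrix(rnorm(12), 2, 6)
  w_t <- project_norm(rnorm(6), 2, 1)
  ctl <- pmfa_control(lambda = 0, directionality = FALSE)
  w <- ccp_subproblem(w_t, Sig, S, ctl)
  g <- drop(Sig %*% w_t)
  expect_equal(w, g / sqrt(sum(g^2)), tolerance = 1e-10)
})

test_that("subproblem with zero covariance returns a steady-state point", {
  net <- make_toy_network("branched")
  n <- ncol(net$S)
  ctl <- pmfa_control(lambda = 5, directionality = FALSE)
  w <- ccp_subproblem(project_norm(rep(1, n), 2, 1), matrix(0, n, n),
                      net$S, ctl)
  expect_lte(sqrt(sum((net$S %*% w)^2)), 1e-8)
})

test_that("subproblem keeps a steady-state rank-1 direction", {
  net <- make_toy_network("chain")
  e <- c(1, 1, 1) / sqrt(3)
  Sig <- tcrossprod(e)
  for (lam in c(0.5, 10, 1000)) {
    ctl <- pmfa_control(lambda = lam, directionality = FALSE)
    w <- ccp_subproblem(e, Sig, net$S, ctl)
    cosang <- abs(sum(w * e)) / sqrt(sum(w^2))
    expect_gt(cosang, 1 - 1e-8)
  }
})

test_that("exact ball solve and projected FISTA agree when the cone is inactive", {
  ## data along the strictly positive chain mode: the optimum is interior
  ## to the nonnegative cone, so the exact ball solve (no directionality)
  ## and projected FISTA (directionality on) must find the same point.
  net <- make_toy_network("chain")
  e <- c(1, 1, 1) / sqrt(3)
  set.seed(32)
  Sig <- 3 * tcrossprod(e) + 0.05 * random_psd(3, 35)
  ctl_free <- pmfa_control(lambda = 2, directionality = FALSE,
                           n_restarts = 5, tol = 1e-10, max_iter = 500)
  ctl_cone <- pmfa_control(lambda = 2, directionality = TRUE,
                           n_restarts = 5, tol = 1e-10, max_iter = 500,
                           inner_max_iter = 3000, inner_tol = 1e-12)
  a <- solve_component(Sig, net$S, ctl_free)
  b <- solve_component(Sig, net$S, ctl_cone, irreversible = rep(TRUE, 3))
  expect_equal(a$objective, b$objective, tolerance = 1e-5)
  expect_equal(abs(sum(a$w * b$w)), 1, tolerance = 1e-4)
})

test_that("lambda = 0 without directionality recovers the top eigenpair", {
  Sig <- diag(c(3, 1))
  ctl <- pmfa_control(lambda = 0, directionality = FALSE, n_restarts = 5,
                      tol = 1e-12, max_iter = 1000)
  cmp <- solve_component(Sig, matrix(0, 1, 2), ctl)
  expect_equal(abs(cmp$w), c(1, 0), tolerance = 1e-6)
  expect_equal(cmp$variance, 3, tolerance = 1e-9)
  ## random PSD case against the dense eigensolver
  Sig2 <- random_psd(8, 33)
  eg <- eigen(Sig2, symmetric = TRUE)
  cmp2 <- solve_component(Sig2, matrix(0, 1, 8), ctl)
  expect_gt(abs(sum(cmp2$w * eg$vectors[, 1])), 1 - 1e-6)
  expect_equal(cmp2$variance, eg$values[1], tolerance = 1e-6)
})

test_that("noise-free single-mode data is recovered for any lambda", {
  net <- make_toy_network("chain")
  ems <- enumerate_ems(net)
  sim <- simulate_flux_data(ems, list(1), samples_per_condition = 8, seed = 3)
  e <- ems$modes[, 1]
  for (lam in c(0, 1, 100)) {
    fit <- pmfa(sim$X, net, lambda = lam, control = fast_control())
    w <- fit$loadings[, 1]
    expect_gt(abs(sum(w * e)) / sqrt(sum(w^2)), 0.999)
    expect_lt(sqrt(fit$deviation_sq[1]), 1e-6)
  }
})

test_that("zero covariance yields a flagged degenerate component", {
  cmp <- solve_component(matrix(0, 3, 3), matrix(0, 1, 3),
                         pmfa_control(lambda = 0, n_restarts = 3))
  expect_true(cmp$degenerate)
  expect_equal(cmp$objective, 0)
  expect_equal(sqrt(sum(cmp$w^2)), 1)
})

test_that("returned components satisfy their constraints exactly", {
  dat <- mini_ccm_sim(noise = 0.05, seed = 8)
  Sig <- flux_covariance(center_columns(dat$sim$X))
  for (p in c(1, 2)) for (q in c(1, 2)) {
    ctl <- pmfa_control(lambda = 1, stoich_norm = q, loading_norm = p,
                        budget = 2, directionality = TRUE, n_restarts = 5)
    cmp <- solve_component(Sig, dat$net$S, ctl,
                           irreversible = !dat$net$reversible)
    nrm <- if (p == 2) sqrt(sum(cmp$w^2)) else sum(abs(cmp$w))
    expect_equal(nrm, ctl$budget, tolerance = 1e-8)
    expect_true(all(cmp$w[!dat$net$reversible] >= -1e-10))
  }
})

test_that("all-irreversible networks give wholly nonnegative loadings", {
  net <- make_toy_network("branched")
  ems <- enumerate_ems(net)
  sim <- simulate_flux_data(ems, list(1, 2, c(1, 2)),
                            samples_per_condition = 4, noise = 0.05, seed = 2)
  fit <- pmfa(sim$X, net, lambda = 1, control = fast_control())
  expect_true(all(fit$loadings >= -1e-10))
})

test_that("the convex surrogate decreases at each accepted subproblem solve", {
  dat <- mini_ccm_sim(noise = 0.05, seed = 12)
  Sig <- flux_covariance(center_columns(dat$sim$X))
  net <- dat$net
  for (q in c(1, 2)) {
    ctl <- pmfa_control(lambda = 2, stoich_norm = q, n_restarts = 1, seed = 5)
    nonneg <- which(!net$reversible)
    set.seed(99)
    w <- rnorm(ncol(Sig)); w[nonneg] <- abs(w[nonneg])
    w <- project_norm(w, 2, 1)
    surrogate <- function(v, w_t) {
      sw <- drop(net$S %*% v)
      pen <- if (q == 2) sum(sw^2) else sum(abs(sw))
      ctl$lambda * pen - 2 * drop(crossprod(w_t, Sig %*% v))
    }
    for (t in 1:8) {
      v <- ccp_subproblem(w, Sig, net$S, ctl, nonneg)
      expect_lte(surrogate(v, w), surrogate(w, w) + 1e-7)
      w <- project_norm(v, 2, 1)
    }
  }
})

test_that("orthonormalization extends the basis correctly", {
  w1 <- c(1, 0, 0)
  expect_equal(orthonormalize_next(matrix(0, 3, 0), w1), w1)
  w2 <- c(0, 2, 0)
  expect_equal(orthonormalize_next(cbind(w1), w2), c(0, 1, 0))
  expect_error(orthonormalize_next(cbind(w1), w1), "linear dependence")
  q <- orthonormalize_next(cbind(w1), c(1, 1, 0))
  expect_equal(sum(q * w1), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(q^2)), 1)
})

test_that("Schur deflation removes variance along q and stays PSD", {
  expect_equal(schur_deflate(diag(3), c(1, 0, 0)),
               diag(c(0, 1, 1)))
  set.seed(41)
  for (rep in 1:15) {
    Sig <- random_psd(6, 41 + rep)
    q <- project_norm(rnorm(6), 2, 1)
    Sd <- schur_deflate(Sig, q)
    expect_equal(Sd, t(Sd))
    expect_gte(min(eigen(Sd, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_equal(drop(crossprod(q, Sd %*% q)), 0, tolerance = 1e-8)
  }
  expect_error(schur_deflate(matrix(0, 2, 2), c(1, 0)), "no variance")
})

test_that("a 1-component fit equals a single solve_component call", {
  dat <- mini_ccm_sim(noise = 0.05, seed = 3)
  ctl <- fast_control(seed = 7)
  ctl$lambda <- 5
  fit <- pmfa(dat$sim$X, dat$net, n_components = 1, control = ctl)
  Xc <- center_columns(dat$sim$X)
  Sig <- flux_covariance(Xc)
  Sig <- Sig[colnames(dat$sim$X), colnames(dat$sim$X)]
  cmp <- solve_component(Sig, dat$net$S, ctl,
                         irreversible = !dat$net$reversible)
  expect_equal(unname(fit$loadings[, 1]), unname(cmp$w))
  expect_equal(fit$components[[1]]$objective, cmp$objective)
})

test_that("two orthogonal steady modes are both recovered", {
  net <- make_toy_network("sparse_embed")
  ems <- enumerate_ems(net)
  ## the pathway mode and one background pair mode have disjoint supports
  supp_sizes <- vapply(ems$supports, length, integer(1))
  big <- which.max(supp_sizes)
  small <- which(supp_sizes == 2)[1]
  sim <- simulate_flux_data(ems, list(big, small, c(big, small)),
                            samples_per_condition = 4, seed = 17)
  fit <- pmfa(sim$X, net, n_components = 2, lambda = 100,
              control = fast_control())
  for (mode in c(big, small)) {
    cors <- apply(fit$loadings, 2, function(w)
      abs(cor(w, ems$modes[, mode])))
    expect_gt(max(cors), 0.99)
  }
})

test_that("additional variance is nonincreasing across components", {
  set.seed(51)
  for (rep in 1:3) {
    dat <- mini_ccm_sim(noise = 0.1, seed = 50 + rep)
    fit <- pmfa(dat$sim$X, dat$net, n_components = 3, lambda = 1,
                control = fast_control())
    expect_true(all(diff(fit$variance_additional) <= 1e-8))
  }
})

test_that("subsystem fit over all reactions equals the plain fit", {
  dat <- mini_ccm_sim(noise = 0.05, seed = 13)
  ctl <- fast_control(seed = 3)
  f1 <- pmfa(dat$sim$X, dat$net, lambda = 2, control = ctl)
  f2 <- pmfa(dat$sim$X, dat$net, lambda = 2, control = ctl,
             subsystem = dat$net$reaction_ids)
  expect_equal(f1$loadings, f2$loadings)
})

test_that("with lambda = 0 loadings vanish outside the subsystem", {
  dat <- mini_ccm_sim(noise = 0.05, seed = 14)
  sub <- subsystem_columns(dat$net, "tca")
  fit <- pmfa(dat$sim$X, dat$net, lambda = 0, subsystem = "tca",
              control = fast_control())
  outside <- setdiff(seq_along(dat$net$reaction_ids), sub)
  expect_true(all(abs(fit$loadings[outside, 1]) < 1e-6))
})

test_that("a single-reaction subsystem with strong regularization recovers the chain mode", {
  net <- make_toy_network("chain")
  ems <- enumerate_ems(net)
  sim <- simulate_flux_data(ems, list(1), samples_per_condition = 8, seed = 3)
  fit <- pmfa(sim$X, net, lambda = 1000, subsystem = "R2",
              control = fast_control())
  expect_equal(unname(abs(fit$loadings[, 1])), rep(1, 3) / sqrt(3),
               tolerance = 1e-3)
})

test_that("hard steady state solves the nullspace-restricted eigenproblem", {
  net <- make_toy_network("chain")
  ems <- enumerate_ems(net)
  sim <- simulate_flux_data(ems, list(1), samples_per_condition = 8,
                            noise = 0.1, seed = 19)
  fit <- pmfa(sim$X, net, hard = TRUE, directionality = FALSE)
  ## chain nullspace is one-dimensional: the full pathway mode
  expect_equal(unname(abs(fit$loadings[, 1])), rep(1, 3) / sqrt(3),
               tolerance = 1e-10)
  expect_lt(fit$deviation_sq[1], 1e-16)
  expect_warning(
    pmfa(sim$X, net, hard = TRUE, directionality = TRUE,
         control = fast_control(n_restarts = 2)),
    "lambda = 1e6")
})

test_that("fits are reproducible bit for bit under a fixed seed", {
  dat <- mini_ccm_sim(noise = 0.05, seed = 23)
  ctl <- fast_control(seed = 11)
  f1 <- pmfa(dat$sim$X, dat$net, lambda = 3, n_components = 2, control = ctl)
  f2 <- pmfa(dat$sim$X, dat$net, lambda = 3, n_components = 2, control = ctl)
  expect_identical(f1$loadings, f2$loadings)
})

test_that("model methods expose loadings, scores and residuals", {
  dat <- mini_ccm_sim(noise = 0.05, seed = 25)
  fit <- pmfa(dat$sim$X, dat$net, lambda = 1, n_components = 2,
              control = fast_control())
  expect_equal(coef(fit), fit$loadings)
  sc <- predict(fit, dat$sim$X)
  expect_equal(dim(sc), c(nrow(dat$sim$X), 2))
  res <- residuals(fit, dat$sim$X)
  ## residuals are orthogonal to the fitted subspace
  expect_lt(max(abs(res %*% fit$Q)), 1e-8)
  expect_output(print(fit), "Principal metabolic flux mode")
  s <- summary(fit)
  expect_s3_class(s, "summary.pmfa")
  expect_output(print(s), "Joint fraction")
})

test_that("serialization writes JSON and CSV loadings", {
  dat <- mini_ccm_sim(noise = 0.05, seed = 26)
  fit <- pmfa(dat$sim$X, dat$net, lambda = 1, control = fast_control())
  dir <- withr::local_tempdir()
  write_pmfa(fit, dir, "m")
  doc <- jsonlite::read_json(file.path(dir, "m.json"))
  expect_equal(length(doc$components), 1)
  expect_equal(doc$config$lambda, 1)
  tab <- utils::read.csv(file.path(dir, "m_loadings.csv"))
  expect_equal(tab$reaction_id, dat$net$reaction_ids)
})
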